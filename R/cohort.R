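#' z-scores of each treatment group against its control
#'
#' For every metric and every non-control group:
#' `z = (mean(treatment) - mean(control)) / sd(control)`.
#' Each dendrite counts as one observation (N = 1 per dendrite). The
#' control SD (not a pooled SD) is the denominator, so z expresses how far
#' the treatment mean sits in *control* units; the sign encodes
#' directionality. A metric with zero control variance yields `NA` with a
#' warning.
#'
#' @param table Data frame with a `group` column and numeric metric
#'   columns (e.g. the `reports` tibble of [run_pipeline()] joined with
#'   group labels). Non-numeric columns other than `group` are ignored.
#' @param control Name of the control group level.
#' @param group Name of the grouping column (default `"group"`).
#' @return A `cep_zscore` tibble: `group`, `metric`, `z`, `n_treatment`,
#'   `n_control`, with attributes recording the standardization choice.
#' @export
cohort_zscores <- function(table, control, group = "group") {
  table <- tibble::as_tibble(table)
  stopifnot(group %in% names(table))
  g <- as.character(table[[group]])
  if (!control %in% g) stop("control group '", control, "' not present")
  metrics <- names(table)[vapply(table, is.numeric, TRUE)]
  metrics <- setdiff(metrics, c(group, "dendrite", "categorical_score"))
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c(group, metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  names(long)[1] <- "group"
  ctrl <- long[long$group == control, ]
  cstat <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$metric),
    c_mean = mean(.data$value, na.rm = TRUE),
    c_sd = stats::sd(.data$value[!is.na(.data$value)]),
    n_control = sum(!is.na(.data$value)), .groups = "drop")
  trt <- long[long$group != control, ]
  tstat <- dplyr::summarise(
    dplyr::group_by(trt, .data$group, .data$metric),
    t_mean = mean(.data$value, na.rm = TRUE),
    n_treatment = sum(!is.na(.data$value)), .groups = "drop")
  out <- dplyr::left_join(tstat, cstat, by = "metric")
  degenerate <- !is.na(out$c_sd) & out$c_sd == 0
  if (any(degenerate))
    warning("zero control variance for metric(s): ",
            paste(unique(out$metric[degenerate]), collapse = ", "),
            "; z set to NA")
  out$z <- ifelse(degenerate | is.na(out$c_sd), NA_real_,
                  (out$t_mean - out$c_mean) / out$c_sd)
  res <- tibble::as_tibble(out[, c("group", "metric", "z",
                                   "n_treatment", "n_control")])
  attr(res, "control") <- control
  attr(res, "standardization") <- "control-SD (not pooled)"
  class(res) <- c("cep_zscore", class(res))
  res
}

#' One-way ANOVA per metric with multiple-comparison correction
#'
#' For every metric, fits a one-way ANOVA across groups and computes
#' either all pairwise comparisons with Bonferroni correction, or
#' comparisons of every group against the control with Dunnett's
#' correction (via the multivariate-t formulation in \pkg{multcomp}).
#' Groups with fewer than two observations are excluded with a warning.
#'
#' @inheritParams cohort_zscores
#' @param method `"bonferroni"` (all pairwise) or `"dunnett"`
#'   (vs control).
#' @param alpha Significance level for the `significant` flag.
#' @return A `cep_comparison` object; `tidy()` returns the comparison
#'   table (`metric`, `comparison`, `estimate`, `p_raw`, `p_adj`,
#'   `significant`), `glance()` the per-metric ANOVA summary.
#' @export
cohort_anova <- function(table, control = NULL,
                         method = c("bonferroni", "dunnett"),
                         group = "group", alpha = 0.05) {
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  stopifnot(group %in% names(table))
  if (method == "dunnett" && is.null(control))
    stop("Dunnett comparisons require a control group")
  g <- as.character(table[[group]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with <2 observations: ",
            paste(small, collapse = ", "))
    table <- table[!(g %in% small), , drop = FALSE]
    g <- as.character(table[[group]])
  }
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups with >=2 observations")
  if (!is.null(control)) {
    if (!control %in% lev) stop("control group '", control, "' not present")
    lev <- c(control, setdiff(lev, control))
  }
  fg <- factor(g, levels = lev)
  metrics <- names(table)[vapply(table, is.numeric, TRUE)]
  metrics <- setdiff(metrics, c(group, "dendrite", "categorical_score"))
  anova_rows <- list(); comp_rows <- list()
  for (m in metrics) {
    y <- table[[m]]
    ok <- !is.na(y)
    if (length(unique(fg[ok])) < 2 || sum(ok) < 3) next
    fit <- stats::aov(y[ok] ~ g., data = data.frame(g. = fg[ok]))
    an <- summary(fit)[[1]]
    anova_rows[[m]] <- tibble::tibble(
      metric = m, df_between = an$Df[1], df_within = an$Df[2],
      f_statistic = an$`F value`[1], p_anova = an$`Pr(>F)`[1])
    if (method == "dunnett") {
      glt <- multcomp::glht(fit, linfct = multcomp::mcp(g. = "Dunnett"))
      sm <- summary(glt)
      raw <- summary(glt, test = multcomp::adjusted("none"))
      comp_rows[[m]] <- tibble::tibble(
        metric = m, comparison = names(sm$test$coefficients),
        estimate = as.numeric(sm$test$coefficients),
        p_raw = as.numeric(raw$test$pvalues),
        p_adj = pmax(as.numeric(sm$test$pvalues),
                     as.numeric(raw$test$pvalues)))
    } else {
      cmp <- pairwise_from_aov(fit, fg[ok], y[ok])
      mnum <- nrow(cmp)
      cmp$p_adj <- pmin(1, cmp$p_raw * mnum)
      cmp$metric <- m
      comp_rows[[m]] <- cmp[, c("metric", "comparison", "estimate",
                                "p_raw", "p_adj")]
    }
  }
  comp <- dplyr::bind_rows(comp_rows)
  comp$significant <- comp$p_adj < alpha
  out <- structure(list(anova = dplyr::bind_rows(anova_rows),
                        comparisons = tibble::as_tibble(comp),
                        method = method, control = control, alpha = alpha),
                   class = "cep_comparison")
  out
}

# pairwise t comparisons using the pooled ANOVA error term
pairwise_from_aov <- function(fit, fg, y) {
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfw <- summary(fit)[[1]]$Df[2]
  lev <- levels(droplevels(fg))
  means <- tapply(y, droplevels(fg), mean)
  ns <- tapply(y, droplevels(fg), length)
  rows <- list()
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      est <- means[j] - means[i]
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tval <- est / se
      p <- 2 * stats::pt(-abs(tval), dfw)
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = paste(lev[j], "-", lev[i]),
        estimate = as.numeric(est), p_raw = as.numeric(p))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.cep_comparison <- function(x, ...) {
  cat(sprintf("<cep_comparison> one-way ANOVA, %s correction%s, %d metric(s)\n",
              x$method,
              if (!is.null(x$control)) paste0(" (control: ", x$control, ")") else "",
              nrow(x$anova)))
  print(x$comparisons)
  invisible(x)
}

#' Tidy a cohort comparison: the comparison table
#' @param x A `cep_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per (metric, comparison).
#' @export
tidy.cep_comparison <- function(x, ...) x$comparisons

#' Glance at a cohort comparison: per-metric ANOVA summary
#' @param x A `cep_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per metric.
#' @export
glance.cep_comparison <- function(x, ...) x$anova
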