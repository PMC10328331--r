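# simulated cohort tables: one row per dendrite, gaussian metrics with
# per-group mean shifts in SD units
sim_cohort <- function(n_per_group, shifts = c(ctrl = 0, trt = 0),
                       seed = 1, metrics = 1L) {
  set.seed(seed)
  dplyr::bind_rows(lapply(names(shifts), function(g) {
    out <- tibble::tibble(group = g)
    out <- out[rep(1, n_per_group), , drop = FALSE]
    for (m in seq_len(metrics))
      out[[paste0("m", m)]] <- stats::rnorm(n_per_group, shifts[[g]], 1)
    out
  }))
}
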