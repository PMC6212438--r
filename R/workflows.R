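#' Same-odorant replicate reproducibility
#'
#' Simulates pairs of independent plate runs of the same odorant at a fixed
#' vapor dilution, quantifies both, and computes the squared Pearson R^2
#' between the per-receptor mean responses of the two runs — the assay's
#' run-to-run reproducibility over the 32-unit panel.
#'
#' @param odorant odorant label.
#' @param dilution vapor dilution (vol/vol).
#' @param n_pairs number of independent run pairs.
#' @param seed root seed; each pair derives two distinct sub-seeds.
#' @param mode quantification mode.
#' @return list with `r2` (per-pair values) and `mean_r2`.
#' @export
replicate_reproducibility <- function(odorant = "AC", dilution = 1e-2,
                                      n_pairs = 10, seed = 1L,
                                      mode = "auc_baseline") {
  r2 <- vapply(seq_len(n_pairs), function(k) {
    r1 <- simulate_panel_day(seed = derive_seed(seed, 1000 + 2 * k),
                             day = "dayA", odorants = odorant,
                             dilution = dilution)
    r2_ <- simulate_panel_day(seed = derive_seed(seed, 1001 + 2 * k),
                              day = "dayB", odorants = odorant,
                              dilution = dilution)
    m1 <- response_means(build_response_matrix(r1, mode = mode))
    m2 <- response_means(build_response_matrix(r2_, mode = mode))
    regression_r2(m1[, 1], m2[rownames(m1), 1])$r_squared
  }, numeric(1))
  list(r2 = r2, mean_r2 = mean(r2))
}

#' Mean cross-day classification accuracy
#'
#' For each of `n_seeds` repetitions, simulates a training day and a test
#' day of the default analog panel (3 replicates x 7 odorants), trains the
#' classifier on day 1 and records the percent accuracy on day 2.
#'
#' @param n_seeds repetitions.
#' @param seed root seed.
#' @param method `"random_forest"` or `"lda"`.
#' @param odorants odorant labels.
#' @param dilution vapor dilution.
#' @param ntree random-forest trees.
#' @return list with `accuracy` (per-seed percent) and `mean_accuracy`.
#' @export
cross_day_accuracy <- function(n_seeds = 20, seed = 1L,
                               method = "random_forest",
                               odorants = analog_odorants(),
                               dilution = 1e-2, ntree = 500) {
  acc <- vapply(seq_len(n_seeds), function(k) {
    d1 <- simulate_panel_day(seed = derive_seed(seed, 3000 + 2 * k),
                             day = "day1", odorants = odorants,
                             dilution = dilution)
    d2 <- simulate_panel_day(seed = derive_seed(seed, 3001 + 2 * k),
                             day = "day2", odorants = odorants,
                             dilution = dilution)
    cross_day_classify(d1, d2, method = method,
                       seed = derive_seed(seed, 5000 + k),
                       ntree = ntree)$accuracy
  }, numeric(1))
  list(accuracy = acc, mean_accuracy = mean(acc))
}

#' AUC-versus-peak quantification concordance at one dilution
#'
#' Simulates the default panel against all odorants at the given dilution,
#' quantifies every well both as baseline AUC and as peak, and returns the
#' squared Pearson correlation between the two response matrices.
#'
#' @param seed root seed.
#' @param dilution vapor dilution.
#' @param odorants odorant labels.
#' @return list with `r2` and the two matrices.
#' @export
auc_peak_agreement <- function(seed = 1L, dilution = 1e-2,
                               odorants = analog_odorants()) {
  run <- simulate_panel_day(seed = derive_seed(seed, 7000), day = "day1",
                            odorants = odorants, dilution = dilution)
  run <- normalize_run(run)
  m_auc <- build_response_matrix(run, mode = "auc_baseline")
  m_peak <- build_response_matrix(run, mode = "peak")
  list(r2 = auc_peak_concordance(m_auc, m_peak),
       m_auc = m_auc, m_peak = m_peak)
}
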