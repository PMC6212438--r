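# small in-code fixtures shared across test files

zero_noise <- function() noise_params(0, 0, 0)

tiny_design <- function(or_ids = c("OR1", "OR2"), odorants = "A",
                        conc = 1e-2, phase = "vapor", replicates = 2L,
                        n_cycles = 5L) {
  panel_design(or_ids = or_ids, control_id = "pCI", odorant_ids = odorants,
               conditions = data.frame(odorant = odorants, phase = phase,
                                       concentration = conc),
               replicates = replicates, n_cycles = n_cycles,
               cycle_interval_s = 90)
}

tiny_affinity <- function(or_id = "OR1", odorant = "A", ec50 = 1e-6,
                          efficacy = 4, hill = 1) {
  affinity_model(data.frame(or_id = or_id, odorant_id = odorant,
                            ec50 = ec50, efficacy = efficacy, hill = hill))
}

empty_affinity <- function() {
  affinity_model(data.frame(or_id = character(), odorant_id = character(),
                            ec50 = numeric(), efficacy = numeric(),
                            hill = numeric()))
}

# hand-built trial table (one row per replicate-level panel vector)
make_trials <- function(centers, n_per = 3, day = "day1", sd = 0.05,
                        seed = 1) {
  set.seed(seed)
  p <- ncol(centers)
  panel <- sprintf("OR%02d", seq_len(p))
  rows <- list()
  for (k in seq_len(nrow(centers))) {
    for (r in seq_len(n_per)) {
      v <- centers[k, ] + stats::rnorm(p, 0, sd)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(odorant = rownames(centers)[k], day = day, replicate = r,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(v, panel))))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "panel") <- panel
  out
}
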