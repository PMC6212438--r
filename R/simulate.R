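#' Hill-type receptor occupancy
#'
#' Fractional occupancy of a receptor at dissolved ligand concentration `c`:
#' `c^n / (c^n + ec50^n)`. This is the generative assumption that drives the
#' plate simulator; it is 0 at c = 0, 0.5 at c = ec50, and tends to 1 as c
#' grows, strictly increasing in c.
#'
#' @param concentration dissolved concentration, mol/L (>= 0; vectorized).
#' @param ec50 half-maximal concentration, mol/L (> 0).
#' @param hill Hill slope (> 0).
#' @return occupancy fraction in \[0, 1\].
#' @examples
#' occupancy(1e-6, ec50 = 1e-6, hill = 1)     # 0.5
#' occupancy(1e-5, ec50 = 1e-6, hill = 1)     # 10/11
#' @export
occupancy <- function(concentration, ec50, hill) {
  if (any(ec50 <= 0)) stop("ec50 must be positive")
  if (any(hill <= 0)) stop("hill slope must be positive")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  r <- (concentration / ec50)^hill
  r / (1 + r)
}

#' Map a vapor dilution to a dissolved concentration
#'
#' Volatile odorant equilibrated above the assay medium dissolves into it
#' before reaching the receptors. The simulator uses a linear map: dissolved
#' mol/L = `partition_coeff * dilution`, with `partition_coeff` the dissolved
#' concentration reached by undiluted odorant.
#'
#' @param dilution vol/vol dilution in (0, 1].
#' @param partition_coeff mol/L reached at dilution 1.
#' @return dissolved concentration, mol/L.
#' @export
vapor_to_dissolved <- function(dilution, partition_coeff) {
  if (any(dilution <= 0 | dilution > 1))
    stop("vapor dilution must lie in (0, 1]")
  if (any(partition_coeff <= 0)) stop("partition_coeff must be positive")
  partition_coeff * dilution
}

#' Apply esterase conversion to a ligand mixture
#'
#' For each substrate -> product conversion, moves `fraction` of the substrate
#' molarity onto the product; total molarity per conversion is conserved.
#' Conversions whose substrate is absent from the mixture are skipped with a
#' warning.
#'
#' @param mix a [ligand_mix()].
#' @param model a [ces1d_model()].
#' @return the converted `ligand_mix`.
#' @examples
#' m <- ligand_mix(c(EA = 1e-5))
#' cm <- ces1d_model(data.frame(substrate = "EA", product = "EG", fraction = 0.5))
#' apply_ces1d(m, cm)  # 5e-6 EA + 5e-6 EG
#' @export
apply_ces1d <- function(mix, model) {
  stopifnot(inherits(model, "ces1d_model"))
  out <- as.numeric(mix)
  names(out) <- names(mix)
  cv <- model$conversions
  for (i in seq_len(nrow(cv))) {
    s <- cv$substrate[i]; p <- cv$product[i]; f <- cv$fraction[i]
    if (!s %in% names(out)) {
      warning("apply_ces1d: substrate ", sQuote(s), " not in mixture; skipped")
      next
    }
    moved <- out[[s]] * f
    out[[s]] <- out[[s]] - moved
    if (!p %in% names(out)) out[p] <- 0
    out[[p]] <- out[[p]] + moved
  }
  ligand_mix(out)
}

# log-normal multiplicative noise with unit mean and given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# counter-based per-well substream seed: a pure function of (root, index) so
# appending wells never perturbs the streams of existing wells
derive_seed <- function(root, index) {
  m <- 2147483629
  x <- ((as.double(root) %% m) * 40503 + as.double(index) * 7919 + 13) %% m
  as.integer(x)
}

# effective efficacy of one receptor facing a ligand mixture: sum of
# efficacy x occupancy over components, capped at the largest single efficacy
# so superposition cannot exceed the strongest full agonist
effective_efficacy <- function(aff_rows, mix) {
  if (nrow(aff_rows) == 0 || length(mix) == 0) return(0)
  idx <- match(aff_rows$odorant_id, names(mix))
  keep <- !is.na(idx)
  if (!any(keep)) return(0)
  conc <- as.numeric(mix)[idx[keep]]
  occ <- occupancy(conc, aff_rows$ec50[keep], aff_rows$hill[keep])
  min(sum(aff_rows$efficacy[keep] * occ), max(aff_rows$efficacy[keep]))
}

#' Simulate one luminescence trace
#'
#' Generates the reads of a single well:
#' `value(i) = gain * baseline * drift^(i-1) * (1 + E * (1 - exp(-k * max(0, t_i - onset)))) * noise_i`
#' with `t_i = (i - 1) * cycle_interval_s` and `E` the toxicity-scaled
#' effective efficacy of the receptor against the dissolved mixture. With
#' zero noise and drift 1 the trace is strictly positive and non-decreasing.
#'
#' @param or_id receptor label (used only for the affinity lookup).
#' @param mix dissolved [ligand_mix()].
#' @param affinity an [affinity_model()].
#' @param kinetics a [kinetic_params()].
#' @param toxicity_scale scalar response attenuation in \[0, 1\].
#' @param n_cycles,cycle_interval_s read schedule.
#' @param gain per-well multiplicative gain.
#' @param read_noise optional vector of per-read multiplicative noise
#'   (length `n_cycles`); default all 1.
#' @return numeric vector of luminescence values, length `n_cycles`.
#' @export
simulate_trace <- function(or_id, mix, affinity, kinetics,
                           toxicity_scale = 1, n_cycles = 20,
                           cycle_interval_s = 90, gain = 1,
                           read_noise = NULL) {
  stopifnot(inherits(affinity, "affinity_model"), inherits(kinetics, "kinetic_params"))
  if (toxicity_scale < 0 || toxicity_scale > 1)
    stop("toxicity_scale must lie in [0, 1]")
  if (is.null(read_noise)) read_noise <- rep(1, n_cycles)
  if (length(read_noise) != n_cycles) stop("read_noise length must equal n_cycles")
  e_eff <- toxicity_scale * effective_efficacy(affinity_for(affinity, or_id), mix)
  i <- seq_len(n_cycles)
  t <- (i - 1) * cycle_interval_s
  rise <- 1 - exp(-kinetics$rise_rate * pmax(0, t - kinetics$onset_delay_s))
  gain * kinetics$baseline_lum * kinetics$control_drift^(i - 1) *
    (1 + e_eff * rise) * read_noise
}

#' Simulate a full kinetic plate run
#'
#' Produces one trace per receptor x condition x replicate (including the
#' vector-control wells) as a long-format table, one row per well per cycle.
#' All randomness flows from `seed` through counter-based per-well
#' substreams, so two calls with identical inputs are bit-identical and
#' appending conditions leaves existing wells untouched.
#'
#' @param design a [panel_design()].
#' @param affinity an [affinity_model()]; the vector control must have no
#'   entries (checked).
#' @param kinetics a [kinetic_params()].
#' @param noise a [noise_params()].
#' @param ces1d optional [ces1d_model()] applied to the dissolved mixture.
#' @param toxicity optional [toxicity_model()].
#' @param partition_coeffs named vector of per-odorant vapor partition
#'   coefficients (mol/L at dilution 1); default 1e-2 for every odorant.
#' @param seed integer root seed.
#' @param day day label recorded in the metadata (cross-day workflows rely
#'   on distinct labels).
#' @param run_id run label.
#' @return Object of class `plate_run`: list with `design`, long `traces`
#'   data frame (run_id, day, well_id, or_id, odorant_id, phase,
#'   concentration, replicate, cycle, time_s, luminescence) and `params`.
#' @export
simulate_plate_run <- function(design, affinity,
                               kinetics = kinetic_params(),
                               noise = noise_params(),
                               ces1d = NULL, toxicity = NULL,
                               partition_coeffs = NULL,
                               seed = 1L, day = "day1", run_id = "run1") {
  if (!inherits(design, "panel_design"))
    stop("`design` must be a panel_design (it names the vector control)")
  stopifnot(inherits(affinity, "affinity_model"))
  if (any(affinity$entries$or_id == design$control_id))
    stop("the vector control must have efficacy 0 for all odorants (no affinity entries)")
  if (is.null(partition_coeffs))
    partition_coeffs <- stats::setNames(rep(1e-2, length(design$odorant_ids)),
                                        design$odorant_ids)

  n_cyc <- design$n_cycles
  conds <- design$conditions
  # per-run (day) gain from substream 0
  set.seed(derive_seed(seed, 0))
  day_gain <- rlnorm_cv(1, noise$day_effect_cv)

  rows <- vector("list", nrow(conds) * length(design$all_ids) * design$replicates)
  well <- 0L
  for (ci in seq_len(nrow(conds))) {
    odor <- conds$odorant[ci]; phase <- conds$phase[ci]
    conc <- conds$concentration[ci]
    if (phase == "vapor") {
      pc <- partition_coeffs[[odor]]
      if (is.null(pc)) stop("no partition coefficient for odorant ", sQuote(odor))
      mix <- ligand_mix(stats::setNames(vapor_to_dissolved(conc, pc), odor))
    } else {
      mix <- ligand_mix(stats::setNames(conc, odor))
    }
    if (!is.null(ces1d)) mix <- apply_ces1d(mix, ces1d)
    tox_scale <- 1
    if (!is.null(toxicity) && phase == "vapor" && conc > toxicity$threshold) {
      fl <- toxicity$viability_floor
      if (odor %in% names(fl)) tox_scale <- fl[[odor]]
    }
    for (or in design$all_ids) {
      for (rep_i in seq_len(design$replicates)) {
        well <- well + 1L
        set.seed(derive_seed(seed, well))
        gain <- rlnorm_cv(1, noise$well_scale_cv)
        rn <- rlnorm_cv(n_cyc, noise$additive_cv)
        vals <- simulate_trace(or, mix, affinity, kinetics,
                               toxicity_scale = tox_scale,
                               n_cycles = n_cyc,
                               cycle_interval_s = design$cycle_interval_s,
                               gain = gain * day_gain, read_noise = rn)
        rows[[well]] <- data.frame(
          run_id = run_id, day = day,
          well_id = sprintf("w%04d", well),
          or_id = or, odorant_id = odor, phase = phase,
          concentration = conc, replicate = rep_i,
          cycle = seq_len(n_cyc),
          time_s = (seq_len(n_cyc) - 1) * design$cycle_interval_s,
          luminescence = vals,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(design = design,
                 traces = do.call(rbind, rows),
                 params = list(kinetics = kinetics, noise = noise,
                               ces1d = ces1d, toxicity = toxicity,
                               partition_coeffs = partition_coeffs,
                               seed = seed, day = day, run_id = run_id)),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  n_wells <- length(unique(x$traces$well_id))
  cat("plate_run", sQuote(x$params$run_id), "day", sQuote(x$params$day),
      "seed", x$params$seed, "\n")
  cat(" ", n_wells, "wells x", x$design$n_cycles, "cycles (",
      nrow(x$traces), "reads )\n")
  invisible(x)
}
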