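#' Default receptor panel labels
#'
#' 31 odorant receptors plus one empty-vector control, mirroring the common
#' 96-well layout of 32 transfection groups in triplicate.
#'
#' @return list with `or_ids` (31 labels) and `control_id`.
#' @export
default_or_panel <- function() {
  list(or_ids = sprintf("OR%02d", 1:31), control_id = "pCI")
}

#' Default odorant set: a structural-analog series
#'
#' Seven structurally related aromatic odorants, labelled by conventional
#' abbreviations: acetophenone (AC), 4-methyl acetophenone (MAC),
#' propiophenone (PP), benzaldehyde (BA), 2-hydroxy acetophenone (HAC),
#' methyl salicylate (MS) and menthone (ME). Discriminating among such
#' analogs is the hard case for a receptor-panel sensor.
#'
#' @return character vector of 7 odorant labels.
#' @export
analog_odorants <- function() c("AC", "MAC", "PP", "BA", "HAC", "MS", "ME")

#' Default generative affinity model for the analog panel
#'
#' A deterministic combinatorial code over 31 receptors x 7 odorants.
#' Each receptor-odorant efficacy is the sum of two components, capped at 8:
#'
#' * a receptor-intrinsic scaffold response (amplitude up to 6.4, fixed
#'   arithmetic pattern over the receptor index) shared by all analogs —
#'   structurally related odorants present the same core scaffold, so a
#'   receptor that binds the scaffold responds to every analog to a similar
#'   degree; this makes some receptors broadly tuned "generalists";
#' * an odorant-specific Gaussian tuning bump (amplitude 5.8, width 3.3)
#'   centered at an odorant-specific position along the receptor axis
#'   (centers 3, 4.8, 8.5, 12.5, 16.5, 20.5, 24.5), so structurally adjacent
#'   analogs (nearby centers) activate overlapping "specialist" subsets.
#'
#' Together the two components reproduce the qualitative correlation
#' structure of an analog panel: cross-analog response profiles correlate at
#' squared-Pearson roughly 0.15-0.9 (closest pair highest), well below
#' replicate reproducibility. Sensitivity co-varies with efficacy (EC50 from
#' about 10^-6.5 mol/L for the strongest pairs to 10^-4 for the weakest),
#' which yields nested activation sets across a dilution series: receptors
#' active at low concentration are a subset of those active at high
#' concentration. Efficacies below 0.1 are dropped (non-responders); all
#' Hill slopes are 1.
#'
#' @param odorants odorant labels; defaults to [analog_odorants()].
#' @param panel receptor panel; defaults to [default_or_panel()].
#' @return an [affinity_model()].
#' @export
default_affinity <- function(odorants = analog_odorants(),
                             panel = default_or_panel()) {
  n_or <- length(panel$or_ids)
  n_od <- length(odorants)
  centers <- c(3, 4.8, 8.5, 12.5, 16.5, 20.5, 24.5)
  centers <- centers[((seq_len(n_od) - 1) %% 7) + 1]
  rows <- list()
  for (j in seq_len(n_od)) {
    for (i in seq_len(n_or)) {
      scaffold <- 6.4 * ((7 * i + 3) %% 11) / 10
      bump <- 5.8 * exp(-((i - centers[j]) / 3.3)^2)
      eff <- min(scaffold + bump, 8)
      if (eff < 0.1) next
      rows[[length(rows) + 1L]] <- data.frame(
        or_id = panel$or_ids[i], odorant_id = odorants[j],
        ec50 = 10^(-4 - 2.5 * min(eff, 6) / 6), efficacy = eff, hill = 1,
        stringsAsFactors = FALSE)
    }
  }
  affinity_model(do.call(rbind, rows))
}

#' Default vapor partition coefficients
#'
#' Linear dilution-to-dissolved map: undiluted vapor equilibrates to
#' 1e-2 mol/L dissolved odorant, so the standard 1e-2 vol/vol dilution
#' yields 1e-4 mol/L (100 uM), commensurate with typical liquid-phase
#' stimulation concentrations.
#'
#' @param odorants odorant labels.
#' @return named numeric vector of mol/L per unit dilution.
#' @export
default_partition <- function(odorants = analog_odorants()) {
  stats::setNames(rep(1e-2, length(odorants)), odorants)
}

#' Toxicity presets for undiluted vapor
#'
#' At undiluted (1e0) exposure harsh odorants (eugenol-like) retain only a
#' quarter of the response while mild ones (methyl-benzoate-like) retain
#' most of it. Attenuation applies only above a 1e-1 dilution.
#'
#' @param odorants odorant labels.
#' @param preset `"harsh"` (floor 0.25) or `"mild"` (floor 0.8), recycled
#'   over odorants; or supply `floors` directly.
#' @param floors optional named numeric vector overriding the preset.
#' @return a [toxicity_model()].
#' @export
default_toxicity <- function(odorants = analog_odorants(),
                             preset = c("mild", "harsh"), floors = NULL) {
  if (is.null(floors)) {
    preset <- match.arg(preset)
    f <- if (preset == "harsh") 0.25 else 0.8
    floors <- stats::setNames(rep(f, length(odorants)), odorants)
  }
  toxicity_model(threshold = 1e-1, viability_floor = floors)
}

#' Default panel design
#'
#' The standard vapor experiment: the 31-OR + control panel in triplicate
#' against each odorant at the given vol/vol dilutions, read every 90 s for
#' 20 cycles.
#'
#' @param odorants odorant labels.
#' @param dilutions vapor dilutions (vol/vol), one condition per
#'   odorant x dilution.
#' @param phase `"vapor"` or `"liquid"` (then `dilutions` are mol/L).
#' @param replicates,n_cycles,cycle_interval_s see [panel_design()].
#' @return a [panel_design()].
#' @export
default_panel_design <- function(odorants = analog_odorants(),
                                 dilutions = 1e-2, phase = "vapor",
                                 replicates = 3L, n_cycles = 20L,
                                 cycle_interval_s = 90) {
  panel <- default_or_panel()
  conds <- expand.grid(odorant = odorants, concentration = dilutions,
                       stringsAsFactors = FALSE)
  conds$phase <- phase
  panel_design(or_ids = panel$or_ids, control_id = panel$control_id,
               odorant_ids = odorants,
               conditions = conds[, c("odorant", "phase", "concentration")],
               replicates = replicates, n_cycles = n_cycles,
               cycle_interval_s = cycle_interval_s)
}

#' Simulate one experimental day at default settings
#'
#' Convenience wrapper: default panel, affinity, kinetics and noise; one
#' plate run covering the given odorants at the given dilution.
#'
#' @param seed integer seed for this day's run.
#' @param day day label.
#' @param odorants odorant labels.
#' @param dilution vapor dilution(s).
#' @param ... passed on to [simulate_plate_run()].
#' @return a `plate_run`.
#' @export
simulate_panel_day <- function(seed, day = "day1",
                               odorants = analog_odorants(),
                               dilution = 1e-2, ...) {
  design <- default_panel_design(odorants = odorants, dilutions = dilution)
  simulate_plate_run(design, default_affinity(odorants = odorants),
                     partition_coeffs = default_partition(odorants),
                     seed = seed, day = day,
                     run_id = paste0("run_", day, "_s", seed), ...)
}
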