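#' Panel design for a kinetic plate run
#'
#' Describes one 96-well style kinetic experiment: which receptors are on the
#' plate (31 ORs plus exactly one empty-vector control in the default panel),
#' which odorant conditions are applied, and the read schedule. Liquid-phase
#' concentrations are molar; vapor-phase concentrations are vol/vol dilutions
#' of odorant in mineral oil in (0, 1].
#'
#' @param or_ids character vector of receptor labels (excluding the control).
#' @param control_id label of the empty-vector control well group.
#' @param odorant_ids character vector of odorant labels.
#' @param conditions data frame with columns `odorant`, `phase`
#'   (`"liquid"` or `"vapor"`) and `concentration` (mol/L for liquid,
#'   vol/vol dilution for vapor).
#' @param replicates wells per receptor x condition (>= 2).
#' @param n_cycles number of luminescence reads per well (>= 2).
#' @param cycle_interval_s seconds between reads; read i occurs at
#'   `(i - 1) * cycle_interval_s`.
#' @return An object of class `panel_design`.
#' @examples
#' pd <- panel_design(
#'   or_ids = c("OR01", "OR02"), odorant_ids = "AC",
#'   conditions = data.frame(odorant = "AC", phase = "vapor", concentration = 1e-2)
#' )
#' @export
panel_design <- function(or_ids, control_id = "pCI", odorant_ids, conditions,
                         replicates = 3L, n_cycles = 20L, cycle_interval_s = 90) {
  stopifnot(is.character(or_ids), length(or_ids) >= 1,
            is.character(control_id), length(control_id) == 1)
  if (control_id %in% or_ids)
    stop("`control_id` must not appear in `or_ids`: the panel has exactly one vector-control label")
  if (anyDuplicated(or_ids))
    stop("duplicated receptor labels in `or_ids`")
  if (!is.data.frame(conditions) ||
      !all(c("odorant", "phase", "concentration") %in% names(conditions)))
    stop("`conditions` must be a data frame with columns odorant, phase, concentration")
  conditions <- as.data.frame(conditions)[, c("odorant", "phase", "concentration")]
  if (!all(conditions$phase %in% c("liquid", "vapor")))
    stop("condition phase must be 'liquid' or 'vapor'")
  if (!all(conditions$odorant %in% odorant_ids))
    stop("condition odorant not listed in `odorant_ids`")
  vap <- conditions$phase == "vapor"
  if (any(conditions$concentration[vap] <= 0 | conditions$concentration[vap] > 1))
    stop("vapor dilutions must lie in (0, 1]")
  if (any(conditions$concentration[!vap] <= 0))
    stop("liquid concentrations must be positive (mol/L)")
  replicates <- as.integer(replicates)
  n_cycles <- as.integer(n_cycles)
  if (replicates < 2) stop("`replicates` must be >= 2")
  if (n_cycles < 2) stop("`n_cycles` must be >= 2")
  if (cycle_interval_s <= 0) stop("`cycle_interval_s` must be positive")
  structure(list(
    or_ids = or_ids, control_id = control_id,
    all_ids = c(or_ids, control_id),
    odorant_ids = odorant_ids, conditions = conditions,
    replicates = replicates, n_cycles = n_cycles,
    cycle_interval_s = cycle_interval_s
  ), class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("panel_design:", length(x$or_ids), "ORs + control", sQuote(x$control_id), "\n")
  cat("  conditions:", nrow(x$conditions), " replicates:", x$replicates,
      " cycles:", x$n_cycles, "@", x$cycle_interval_s, "s\n")
  invisible(x)
}

#' Generative receptor-odorant affinity model
#'
#' Each entry gives Hill-type parameters for one receptor-odorant pair:
#' `ec50` (mol/L, dissolved concentration at half-maximal occupancy),
#' `efficacy` (maximal fold-increase in luminescence over baseline, >= 0) and
#' `hill` (slope, > 0). Pairs with no entry are non-responders (efficacy 0);
#' the vector control carries no entries by construction.
#'
#' @param entries data frame with columns `or_id`, `odorant_id`, `ec50`,
#'   `efficacy`, `hill`.
#' @return Object of class `affinity_model`.
#' @export
affinity_model <- function(entries) {
  need <- c("or_id", "odorant_id", "ec50", "efficacy", "hill")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    stop("`entries` must be a data frame with columns ", paste(need, collapse = ", "))
  entries <- as.data.frame(entries)[, need]
  if (any(entries$ec50 <= 0)) stop("ec50 must be positive")
  if (any(entries$hill <= 0)) stop("hill slope must be positive")
  if (any(entries$efficacy < 0)) stop("efficacy must be >= 0")
  if (anyDuplicated(entries[, c("or_id", "odorant_id")]))
    stop("duplicated (or_id, odorant_id) entry")
  structure(list(entries = entries), class = "affinity_model")
}

# rows of the affinity table for one receptor (zero rows for non-responders
# and for the vector control)
affinity_for <- function(model, or_id) {
  e <- model$entries
  e[e$or_id == or_id, , drop = FALSE]
}

#' Kinetic parameters of the luminescence rise
#'
#' The generative trace model is a single-exponential saturating rise over a
#' positive baseline: traces climb monotonically to a plateau, as odor-evoked
#' cAMP reporter signals do over a 30-minute read.
#'
#' @param baseline_lum baseline luminescence (arbitrary units, > 0).
#' @param rise_rate first-order rate constant k (per second, > 0).
#' @param onset_delay_s delay before the rise starts (seconds, >= 0).
#' @param control_drift multiplicative per-cycle drift applied to all wells,
#'   in (0.9, 1.1); 1 means no drift.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(baseline_lum = 100, rise_rate = 0.002,
                           onset_delay_s = 0, control_drift = 1.0) {
  if (baseline_lum <= 0) stop("baseline_lum must be positive")
  if (rise_rate <= 0) stop("rise_rate must be positive")
  if (onset_delay_s < 0) stop("onset_delay_s must be >= 0")
  if (control_drift <= 0.9 || control_drift >= 1.1)
    stop("control_drift must lie in (0.9, 1.1)")
  structure(list(baseline_lum = baseline_lum, rise_rate = rise_rate,
                 onset_delay_s = onset_delay_s, control_drift = control_drift),
            class = "kinetic_params")
}

#' Noise parameters of the plate simulator
#'
#' Three multiplicative log-normal noise sources: a per-well gain (surrogate
#' for transfection-efficiency variation), a per-read measurement noise, and
#' a per-run (day) gain shared by all wells of a run. All are expressed as
#' coefficients of variation; 0 disables a source.
#'
#' @param well_scale_cv CV of the per-well gain.
#' @param additive_cv CV of the per-read noise.
#' @param day_effect_cv CV of the per-run gain.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(well_scale_cv = 0.10, additive_cv = 0.03,
                         day_effect_cv = 0.05) {
  if (any(c(well_scale_cv, additive_cv, day_effect_cv) < 0))
    stop("noise CVs must be >= 0")
  structure(list(well_scale_cv = well_scale_cv, additive_cv = additive_cv,
                 day_effect_cv = day_effect_cv), class = "noise_params")
}

#' Dissolved ligand mixture
#'
#' Named vector of dissolved odorant concentrations (mol/L) seen by the
#' receptors in one well.
#'
#' @param components named numeric vector, concentrations >= 0 in mol/L.
#' @export
ligand_mix <- function(components) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("`components` must be a named numeric vector")
  if (any(components < 0)) stop("concentrations must be >= 0")
  structure(as.numeric(components), names = names(components), class = "ligand_mix")
}

#' Esterase (Ces1d-style) conversion model
#'
#' Carboxyl esterases in the olfactory mucosa hydrolyze ester odorants into
#' alcohol and acid products, so the ligand mixture reaching the receptors
#' differs from the delivered odorant. The model converts a fixed fraction of
#' each substrate into a single product, conserving total molarity.
#'
#' @param conversions data frame with columns `substrate`, `product`,
#'   `fraction` (each in \[0, 1\]).
#' @return Object of class `ces1d_model`.
#' @export
ces1d_model <- function(conversions) {
  need <- c("substrate", "product", "fraction")
  if (!is.data.frame(conversions) || !all(need %in% names(conversions)))
    stop("`conversions` needs columns substrate, product, fraction")
  conversions <- as.data.frame(conversions)[, need]
  if (any(conversions$fraction < 0 | conversions$fraction > 1))
    stop("conversion fractions must lie in [0, 1]")
  if (anyDuplicated(conversions$substrate))
    stop("one product per substrate: duplicated substrate")
  structure(list(conversions = conversions), class = "ces1d_model")
}

#' High-dose toxicity attenuation
#'
#' Undiluted odorant vapor reduces cell viability (a 75 percent viability loss
#' is typical for a harsh odorant such as eugenol, a mild one loses far less),
#' which the simulator models as a scalar attenuation of the evoked response
#' at vapor dilutions above `threshold`.
#'
#' @param threshold vol/vol dilution above which attenuation applies
#'   (default 1e-1, so effectively only the undiluted 1e0 condition).
#' @param viability_floor named vector (per odorant) of response fraction
#'   retained at undiluted exposure, each in \[0, 1\]; odorants without an
#'   entry are unaffected.
#' @return Object of class `toxicity_model`.
#' @export
toxicity_model <- function(threshold = 1e-1, viability_floor = numeric()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (length(viability_floor) &&
      (any(viability_floor < 0 | viability_floor > 1)))
    stop("viability_floor values must lie in [0, 1]")
  if (length(viability_floor) && is.null(names(viability_floor)))
    stop("viability_floor must be named by odorant")
  structure(list(threshold = threshold, viability_floor = viability_floor),
            class = "toxicity_model")
}
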