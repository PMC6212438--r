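#' Normalize a kinetic trace against vector-control wells
#'
#' Two-step normalization used throughout the vapor assay: (1) divide each
#' well's reads by its own cycle-1 value, removing per-well gain; (2) divide
#' by the per-cycle mean of the (equally initial-normalized) empty-vector
#' control wells, removing shared drift and reagent decay. The result is
#' dimensionless with cycle 1 exactly 1.
#'
#' @param values raw luminescence reads of one well (all > 0).
#' @param controls raw control reads: a vector (one control well) or matrix
#'   with one row per control well and one column per cycle.
#' @param well_id optional label used in error messages.
#' @return normalized trace, same length as `values`.
#' @examples
#' normalize_trace(c(100, 150, 200), c(100, 110, 121))
#' @export
normalize_trace <- function(values, controls, well_id = NULL) {
  if (is.vector(controls)) controls <- matrix(controls, nrow = 1)
  if (ncol(controls) != length(values))
    stop("control traces and trace must share the cycle structure")
  if (any(values <= 0))
    stop("non-positive luminescence in well ",
         if (is.null(well_id)) "" else sQuote(well_id))
  if (any(controls <= 0))
    stop("non-positive luminescence in a control trace")
  v <- values / values[1]
  cn <- sweep(controls, 1, controls[, 1], "/")
  v / colMeans(cn)
}

#' Normalize every trace of a plate run
#'
#' Applies [normalize_trace()] well-by-well, normalizing each well against
#' the vector-control wells of the same condition within the same run.
#'
#' @param run a `plate_run` (simulated or read from CSV).
#' @return the run with a `norm` column added to `traces`.
#' @export
normalize_run <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  tr <- run$traces
  ctrl_id <- run$design$control_id
  key <- paste(tr$odorant_id, tr$phase, tr$concentration, sep = "\r")
  tr$norm <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    sub <- tr[sel, ]
    ctrl <- sub[sub$or_id == ctrl_id, ]
    if (nrow(ctrl) == 0)
      stop("no vector-control wells for condition ", sQuote(gsub("\r", "/", k)))
    # controls as rows = control wells, cols = cycles (cycle-sorted)
    cmat <- t(vapply(split(seq_len(nrow(ctrl)), ctrl$well_id), function(ix) {
      v <- ctrl$luminescence[ix][order(ctrl$cycle[ix])]
      v
    }, numeric(run$design$n_cycles)))
    for (w in unique(sub$well_id)) {
      ix <- which(sel)[sub$well_id == w]
      ord <- order(tr$cycle[ix])
      tr$norm[ix[ord]] <- normalize_trace(tr$luminescence[ix[ord]], cmat,
                                          well_id = w)
    }
  }
  run$traces <- tr
  run
}

#' Response quantification: summed normalized luminescence (AUC)
#'
#' The scalar response of a well is the sum of its normalized luminescence
#' over all cycles. In `"raw"` mode this is the plain sum; in `"baseline"`
#' mode the constant resting level of 1 per cycle is subtracted, so a null
#' (control-like) trace quantifies to 0. The sum is unweighted by time.
#'
#' @param ntrace normalized trace (cycle 1 = 1).
#' @param mode `"baseline"` (default) or `"raw"`.
#' @return scalar response value.
#' @examples
#' auc(c(1, 1.5, 2))               # baseline: 1.5
#' auc(c(1, 1.5, 2), mode = "raw") # 4.5
#' @export
auc <- function(ntrace, mode = c("baseline", "raw")) {
  mode <- match.arg(mode)
  s <- sum(ntrace)
  if (mode == "baseline") s - length(ntrace) else s
}

#' Response quantification: peak normalized luminescence
#'
#' Maximum normalized value across cycles (`"raw"`), or that maximum minus
#' the resting level of 1 (`"baseline"`).
#'
#' @inheritParams auc
#' @return scalar peak value.
#' @export
peak <- function(ntrace, mode = c("raw", "baseline")) {
  mode <- match.arg(mode)
  m <- max(ntrace)
  if (mode == "baseline") m - 1 else m
}

quantify_well <- function(ntrace, mode) {
  switch(mode,
         auc_baseline = auc(ntrace, "baseline"),
         auc_raw = auc(ntrace, "raw"),
         peak = peak(ntrace, "raw"),
         stop("unknown quantification mode ", sQuote(mode)))
}

#' Assemble a response matrix from plate runs
#'
#' Normalizes each run, quantifies every well (including the vector-control
#' wells) and assembles the receptor x condition response matrix with full
#' replicate structure. Cells pool the replicates of all supplied runs; the
#' tidy table retains run and day labels for per-day analyses.
#'
#' @param runs a `plate_run` or list of them (sharing the panel design).
#' @param mode quantification mode: `"auc_baseline"` (default), `"auc_raw"`
#'   or `"peak"`.
#' @return Object of class `response_matrix`: list with `tidy` (or_id,
#'   odorant_id, phase, concentration, condition, day, run_id, replicate,
#'   value), `summary` (per or_id x condition: mean, sem = sd/sqrt(n), n)
#'   and `mode`.
#' @export
build_response_matrix <- function(runs, mode = c("auc_baseline", "auc_raw", "peak")) {
  mode <- match.arg(mode)
  if (inherits(runs, "plate_run")) runs <- list(runs)
  tidies <- lapply(runs, function(run) {
    if (is.null(run$traces$norm)) run <- normalize_run(run)
    tr <- run$traces
    wk <- paste(tr$well_id, tr$run_id, sep = "\r")
    out <- lapply(split(seq_len(nrow(tr)), wk), function(ix) {
      v <- tr$norm[ix][order(tr$cycle[ix])]
      r <- tr[ix[1], c("or_id", "odorant_id", "phase", "concentration",
                       "day", "run_id", "replicate")]
      r$value <- quantify_well(v, mode)
      r
    })
    do.call(rbind, out)
  })
  tidy <- do.call(rbind, tidies)
  rownames(tidy) <- NULL
  tidy$condition <- condition_key(tidy$odorant_id, tidy$phase, tidy$concentration)
  agg_mean <- stats::aggregate(value ~ or_id + condition, tidy, mean)
  agg_sd <- stats::aggregate(value ~ or_id + condition, tidy, stats::sd)
  agg_n <- stats::aggregate(value ~ or_id + condition, tidy, length)
  s <- agg_mean
  names(s)[names(s) == "value"] <- "mean"
  s$sem <- agg_sd$value / sqrt(agg_n$value)
  s$n <- agg_n$value
  structure(list(tidy = tidy, summary = s, mode = mode,
                 control_id = runs[[1]]$design$control_id),
            class = "response_matrix")
}

# canonical condition key; dilutions rendered as exact decade-style strings
condition_key <- function(odorant, phase, concentration) {
  paste(odorant, phase, sprintf("%.6g", concentration), sep = "|")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("response_matrix (", x$mode, "): ",
      length(unique(x$summary$or_id)), " receptors x ",
      length(unique(x$summary$condition)), " conditions\n", sep = "")
  invisible(x)
}

#' Wide matrix of per-cell means
#'
#' @param x a `response_matrix`.
#' @return numeric matrix, rows = receptor labels (sorted, control last),
#'   columns = condition keys.
#' @export
response_means <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  s <- x$summary
  ors <- sort(unique(s$or_id))
  ors <- c(setdiff(ors, x$control_id), intersect(x$control_id, ors))
  conds <- sort(unique(s$condition))
  m <- matrix(NA_real_, length(ors), length(conds),
              dimnames = list(ors, conds))
  m[cbind(match(s$or_id, ors), match(s$condition, conds))] <- s$mean
  m
}

#' Concordance between two quantification modes
#'
#' Squared Pearson correlation between the per-cell means of two response
#' matrices over the same receptors and conditions — e.g. AUC-based versus
#' peak-based quantification of the same runs.
#'
#' @param m1,m2 `response_matrix` objects sharing rows and columns.
#' @return squared Pearson R^2 in \[0, 1\].
#' @export
auc_peak_concordance <- function(m1, m2) {
  stopifnot(inherits(m1, "response_matrix"), inherits(m2, "response_matrix"))
  a <- m1$summary; b <- m2$summary
  key <- function(s) paste(s$or_id, s$condition, sep = "\r")
  j <- match(key(a), key(b))
  if (anyNA(j)) stop("matrices do not share rows/columns")
  if (nrow(a) < 3) stop("need at least 3 paired cells")
  stats::cor(a$mean, b$mean[j])^2
}
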