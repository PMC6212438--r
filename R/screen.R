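#' Dual-reporter normalized activity
#'
#' Firefly luciferase luminescence divided by Renilla luciferase
#' luminescence from the same well, controlling for transfection efficiency.
#'
#' @param firefly firefly luminescence (arbitrary units).
#' @param renilla Renilla luminescence (> 0).
#' @return dimensionless activity, vectorized.
#' @export
reporter_activity <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("Renilla luminescence must be positive")
  firefly / renilla
}

check_screen_records <- function(records) {
  need <- c("or_id", "odorant_id", "concentration", "replicate",
            "firefly", "renilla")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("screen records need columns ", paste(need, collapse = ", "))
  records$activity <- reporter_activity(records$firefly, records$renilla)
  records
}

#' Primary screen: fold-change ranking
#'
#' For every receptor-odorant pair, the fold change is the mean odor-evoked
#' activity over the mean no-odor (medium alone) activity of the same
#' receptor. Pairs are ranked by descending fold change, ties broken by
#' receptor then odorant label, and candidates selected either as the top k
#' pairs or by a fold-change threshold.
#'
#' @param records screen table: columns `or_id`, `odorant_id`,
#'   `concentration` (mol/L; `NA` marks no-odor control rows, whose
#'   `odorant_id` is ignored), `replicate`, `firefly`, `renilla`.
#' @param select_rule either `list(type = "top", k = <int>)` or
#'   `list(type = "fold", threshold = <num>)`. Default fold >= 2.
#' @return data frame of pairs with `fold`, `rank`, `candidate`,
#'   `unrankable` (no-odor mean zero), sorted by rank.
#' @export
primary_rank <- function(records, select_rule = list(type = "fold", threshold = 2)) {
  records <- check_screen_records(records)
  ctrl <- records[is.na(records$concentration), ]
  odor <- records[!is.na(records$concentration), ]
  if (nrow(odor) == 0 || nrow(ctrl) == 0)
    stop("records must contain both odor and no-odor rows")
  ctrl_mean <- tapply(ctrl$activity, ctrl$or_id, mean)
  pk <- paste(odor$or_id, odor$odorant_id, sep = "\r")
  odor_mean <- tapply(odor$activity, pk, mean)
  ids <- do.call(rbind, strsplit(names(odor_mean), "\r", fixed = TRUE))
  res <- data.frame(or_id = ids[, 1], odorant_id = ids[, 2],
                    odor_mean = as.numeric(odor_mean),
                    stringsAsFactors = FALSE)
  res$control_mean <- as.numeric(ctrl_mean[res$or_id])
  if (anyNA(res$control_mean))
    stop("missing no-odor control for some receptors")
  res$unrankable <- res$control_mean == 0
  res$fold <- ifelse(res$unrankable, NA_real_, res$odor_mean / res$control_mean)
  ord <- order(-ifelse(is.na(res$fold), -Inf, res$fold), res$or_id, res$odorant_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  res$candidate <- switch(select_rule$type,
    top = res$rank <= select_rule$k & !res$unrankable,
    fold = !res$unrankable & res$fold >= select_rule$threshold,
    stop("select_rule$type must be 'top' or 'fold'"))
  rownames(res) <- NULL
  res
}

#' Secondary screen: triplicate t-test confirmation
#'
#' Candidate pairs are re-tested at a small dose series (canonically 1, 10
#' and 100 uM) in triplicate against triplicate no-odor controls. A pair is
#' confirmed if, at any dose, a two-sided two-sample t-test (Welch by
#' default) gives p < `alpha` uncorrected and the odor mean exceeds the
#' control mean (suppressions do not count as hits).
#'
#' @param records secondary screen table, same columns as [primary_rank()].
#' @param candidates optional data frame with `or_id`, `odorant_id` (e.g.
#'   the candidate rows of [primary_rank()]); defaults to all pairs present.
#' @param alpha significance level, default 0.05 (uncorrected).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data frame per pair: `confirmed`, and per-dose columns `p_<dose>`.
#' @export
secondary_confirm <- function(records, candidates = NULL, alpha = 0.05,
                              var_equal = FALSE) {
  records <- check_screen_records(records)
  ctrl <- records[is.na(records$concentration), ]
  odor <- records[!is.na(records$concentration), ]
  if (is.null(candidates)) {
    candidates <- unique(odor[, c("or_id", "odorant_id")])
  } else {
    candidates <- unique(as.data.frame(candidates)[, c("or_id", "odorant_id")])
  }
  doses <- sort(unique(odor$concentration))
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    or <- candidates$or_id[i]; od <- candidates$odorant_id[i]
    cvals <- ctrl$activity[ctrl$or_id == or]
    if (length(cvals) < 2)
      stop("fewer than 2 control replicates for ", sQuote(or))
    row <- list(or_id = or, odorant_id = od)
    confirmed <- FALSE
    for (d in doses) {
      ovals <- odor$activity[odor$or_id == or & odor$odorant_id == od &
                               odor$concentration == d]
      if (length(ovals) == 0) { row[[paste0("p_", format(d))]] <- NA_real_; next }
      if (length(ovals) < 2)
        stop("fewer than 2 odor replicates for ", sQuote(or), " x ", sQuote(od),
             " at ", format(d))
      p <- safe_t_p(ovals, cvals, var_equal)
      row[[paste0("p_", format(d))]] <- p
      if (p < alpha && mean(ovals) > mean(cvals)) confirmed <- TRUE
    }
    row$confirmed <- confirmed
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen summary counts
#'
#' Per-odorant confirmed-pair counts, the overall confirmed-pair count, and
#' the number of distinct receptors confirmed for at least one odorant.
#'
#' @param results output of [secondary_confirm()].
#' @return list with `per_odorant` (named counts), `n_confirmed_pairs`,
#'   `n_unique_ors`.
#' @export
screen_summary <- function(results) {
  conf <- results[results$confirmed, , drop = FALSE]
  odorants <- unique(results$odorant_id)
  per <- vapply(odorants, function(od) sum(conf$odorant_id == od), integer(1))
  list(per_odorant = per,
       n_confirmed_pairs = nrow(conf),
       n_unique_ors = length(unique(conf$or_id)))
}

#' Simulate a dual-luciferase screen with planted responders
#'
#' Generates screen records for testing the cascade: every receptor gets
#' no-odor control wells; responders (planted truth) get Hill-type
#' dose-dependent activity increases, everything else is null. Renilla
#' readings model transfection variability; all noise is log-normal.
#'
#' @param or_ids receptor labels.
#' @param odorant_ids odorant labels.
#' @param responders data frame `or_id`, `odorant_id`, `effect` (maximal
#'   fold-increase) and optionally `ec50` (default 1e-5 mol/L).
#' @param doses dose series in mol/L; no-odor controls always included.
#' @param replicates wells per receptor x odorant x dose.
#' @param noise_cv CV of activity noise (0 gives deterministic records).
#' @param seed integer seed.
#' @return screen records data frame (see [primary_rank()]).
#' @export
simulate_screen <- function(or_ids, odorant_ids, responders,
                            doses = c(1e-6, 1e-5, 1e-4), replicates = 3,
                            noise_cv = 0.05, seed = 1L) {
  if (!all(c("or_id", "odorant_id", "effect") %in% names(responders)))
    stop("responders needs columns or_id, odorant_id, effect")
  if (is.null(responders$ec50)) responders$ec50 <- rep(1e-5, nrow(responders))
  set.seed(derive_seed(seed, 1))
  rows <- list()
  add <- function(or, od, conc, mu) {
    ren <- rlnorm_cv(replicates, 0.2) * 100
    act <- mu * rlnorm_cv(replicates, noise_cv)
    rows[[length(rows) + 1L]] <<- data.frame(
      or_id = or, odorant_id = od, concentration = conc,
      replicate = seq_len(replicates),
      firefly = act * ren, renilla = ren, stringsAsFactors = FALSE)
  }
  for (or in or_ids) {
    add(or, NA_character_, NA_real_, 1)   # medium-alone controls
    for (od in odorant_ids) {
      hit <- responders[responders$or_id == or & responders$odorant_id == od, ]
      for (d in doses) {
        mu <- if (nrow(hit) == 1)
          1 + hit$effect * occupancy(d, hit$ec50, 1) else 1
        add(or, od, d, mu)
      }
    }
  }
  do.call(rbind, rows)
}
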