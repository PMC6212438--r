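# two-sided two-sample t-test p-value robust to (near-)zero variance: when
# both groups are numerically constant the p degenerates to 1 (equal means)
# or 0 (separated means)
safe_t_p <- function(a, b, var_equal = FALSE) {
  p <- tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                error = function(e) NULL)
  if (!is.null(p)) return(p)
  if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
}

#' One-way ANOVA on response groups
#'
#' Classical fixed-effects one-way analysis of variance over k groups of
#' replicate response values: F = MSbetween / MSwithin with degrees of
#' freedom (k - 1, N - k). Seven odorants in triplicate therefore give
#' df (6, 14). The degenerate all-constant case (zero between- and
#' within-group variance) is reported as F = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 replicates")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- suppressWarnings(stats::anova(stats::aov(value ~ grp)))
  ssb <- tab[["Sum Sq"]][1]; ssw <- tab[["Sum Sq"]][2]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  eps <- .Machine$double.eps * max(sum(value^2), 1)
  if (ssb <= eps) {                  # no between-group signal (incl. all-constant)
    f <- 0; p <- 1
  } else if (ssw <= eps) {           # perfect separation, zero residual
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df_between = df1, df_within = df2, p = p)
}

#' Upper critical value of the F distribution
#'
#' The threshold an observed one-way ANOVA F statistic must exceed for
#' significance at level `alpha`: the (1 - alpha) quantile of
#' F(df1, df2). At df (6, 14) and alpha 0.05 this is 2.85 (2 d.p.).
#'
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qf(1 - alpha, df1, df2)
}

#' Tukey HSD all-pairwise comparisons
#'
#' Studentized-range adjusted pairwise comparisons following a one-way
#' ANOVA; the standard post hoc test for "which odorant pairs does this
#' receptor distinguish". For two groups the adjusted p equals the pooled
#' two-sample t-test p (q = t * sqrt(2)). Degenerate all-identical groups
#' are reported with adjusted p = 1.
#'
#' @param groups list of named (or auto-named) numeric vectors, length >= 2
#'   each.
#' @param conf_level confidence level of the intervals.
#' @return data frame: `group1`, `group2`, `diff` (mean of group2 - group1),
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 replicates")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  th <- stats::TukeyHSD(stats::aov(value ~ grp), conf.level = conf_level)$grp
  pairs <- do.call(rbind, strsplit(rownames(th), "-", fixed = TRUE))
  out <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                    diff = th[, "diff"], lwr = th[, "lwr"], upr = th[, "upr"],
                    p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  out$p_adj[!is.finite(out$p_adj)] <- 1   # zero within-group variance, equal means
  rownames(out) <- NULL
  out
}

#' Differential-activation counts per odorant pair
#'
#' For each receptor, runs a one-way ANOVA of its responses across the
#' odorants and, when significant, Tukey HSD across all odorant pairs; for
#' each pair counts the receptors with adjusted p < `alpha`. This is the
#' panel-level summary "how many receptors tell odorant A from odorant B".
#'
#' @param rm a `response_matrix` restricted to one concentration (one
#'   condition per odorant).
#' @param alpha significance level for both the ANOVA gate and Tukey.
#' @return list with `counts` (symmetric odorant x odorant integer matrix),
#'   `anova` (per-receptor ANOVA results) and `n_anova_significant`.
#' @export
differential_activation_counts <- function(rm, alpha = 0.05) {
  stopifnot(inherits(rm, "response_matrix"))
  tidy <- rm$tidy
  odorants <- sort(unique(tidy$odorant_id))
  if (length(unique(paste(tidy$odorant_id, tidy$concentration))) >
      length(odorants))
    stop("restrict the response matrix to a single concentration first")
  if (length(odorants) < 2) stop("need >= 2 odorant columns")
  counts <- matrix(0L, length(odorants), length(odorants),
                   dimnames = list(odorants, odorants))
  anovas <- list()
  for (or in unique(tidy$or_id)) {
    sub <- tidy[tidy$or_id == or, ]
    groups <- split(sub$value, factor(sub$odorant_id, levels = odorants))
    a <- one_way_anova(groups)
    anovas[[or]] <- a
    if (a$p >= alpha) next
    th <- tukey_hsd(groups)
    sig <- th[th$p_adj < alpha, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      g1 <- sig$group1[i]; g2 <- sig$group2[i]
      counts[g1, g2] <- counts[g1, g2] + 1L
      counts[g2, g1] <- counts[g2, g1] + 1L
    }
  }
  list(counts = counts, anova = anovas,
       n_anova_significant = sum(vapply(anovas, function(a) a$p < alpha,
                                        logical(1))))
}

#' Onset analysis: earliest cycle significantly above baseline
#'
#' One-way ANOVA across cycles; if significant, Dunnett many-to-one
#' comparisons of every cycle against the baseline cycle using the
#' equicorrelated multivariate-t adjustment (correlation 1/2 under a
#' balanced design). The onset is the earliest cycle with adjusted
#' p < `alpha` and a positive mean difference.
#'
#' @param timecourse data frame with columns `cycle` and `value` (>= 2
#'   replicates per cycle), or a matrix with one column per cycle.
#' @param baseline_cycle reference cycle (default the first).
#' @param alpha significance level.
#' @param seed seed for the quasi-Monte-Carlo multivariate-t integration.
#' @return list with `onset` (cycle index or `NA` if no onset), `anova`,
#'   and `comparisons` (cycle, estimate, p_adj).
#' @export
dunnett_onset <- function(timecourse, baseline_cycle = NULL, alpha = 0.05,
                          seed = 1L) {
  if (is.matrix(timecourse)) {
    cyc <- if (is.null(colnames(timecourse))) seq_len(ncol(timecourse))
           else as.numeric(colnames(timecourse))
    timecourse <- data.frame(cycle = rep(cyc, each = nrow(timecourse)),
                             value = as.vector(timecourse))
  }
  stopifnot(all(c("cycle", "value") %in% names(timecourse)))
  if (min(table(timecourse$cycle)) < 2)
    stop("need >= 2 replicates per cycle")
  cycles <- sort(unique(timecourse$cycle))
  if (is.null(baseline_cycle)) baseline_cycle <- cycles[1]
  a <- one_way_anova(split(timecourse$value, timecourse$cycle))
  if (a$p >= alpha)
    return(list(onset = NA_integer_, anova = a, comparisons = NULL))
  lev <- c(baseline_cycle, setdiff(cycles, baseline_cycle))
  dat <- data.frame(value = timecourse$value,
                    cycle = factor(timecourse$cycle, levels = lev))
  fit <- stats::aov(value ~ cycle, data = dat)
  set.seed(seed)  # reproducible mvt quadrature inside multcomp
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(cycle = "Dunnett"))
  sm <- summary(gl)
  comp <- data.frame(cycle = setdiff(lev, baseline_cycle),
                     estimate = as.numeric(sm$test$coefficients),
                     p_adj = as.numeric(sm$test$pvalues))
  comp <- comp[order(comp$cycle), ]
  hit <- comp$cycle[comp$p_adj < alpha & comp$estimate > 0]
  list(onset = if (length(hit)) min(hit) else NA_integer_,
       anova = a, comparisons = comp)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (same order as input).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Effect of enzyme co-expression on the response matrix
#'
#' Compares matched receptor x odorant cells of two response matrices
#' (without and with esterase co-expression): fold change of mean responses,
#' two-sided t-test per cell (Welch by default), and BH FDR adjustment
#' across the receptor panel within each odorant.
#'
#' @param m_without,m_with `response_matrix` objects with matched cells and
#'   >= 2 replicates each.
#' @param alpha significance level on the adjusted p-values.
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @return data frame: `or_id`, `odorant_id`, `condition`, `fold`
#'   (mean with / mean without; `NA` and flagged when the denominator mean
#'   is not positive), `p`, `p_adj`, `direction` (+1/-1), `significant`.
#' @export
ces1d_compare <- function(m_without, m_with, alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(m_without, "response_matrix"),
            inherits(m_with, "response_matrix"))
  key <- function(t) paste(t$or_id, t$condition, sep = "\r")
  t0 <- m_without$tidy; t1 <- m_with$tidy
  cells <- unique(t0[, c("or_id", "odorant_id", "condition")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- paste(cells$or_id[i], cells$condition[i], sep = "\r")
    v0 <- t0$value[key(t0) == k]
    v1 <- t1$value[key(t1) == k]
    if (length(v1) < 2 || length(v0) < 2)
      stop("need >= 2 replicates in both matrices for every cell")
    p <- safe_t_p(v1, v0, var_equal)
    out[[i]] <- data.frame(
      or_id = cells$or_id[i], odorant_id = cells$odorant_id[i],
      condition = cells$condition[i],
      fold = if (mean(v0) > 0) mean(v1) / mean(v0) else NA_real_,
      fold_undefined = mean(v0) <= 0,
      p = p, direction = sign(mean(v1) - mean(v0)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  for (od in unique(res$odorant_id)) {     # FDR family: panel within odorant
    sel <- res$odorant_id == od
    res$p_adj[sel] <- bh_fdr(res$p[sel])
  }
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Ordinary least-squares regression with squared-Pearson R^2
#'
#' Simple linear regression y ~ x reporting slope, intercept, R^2 (the
#' squared Pearson correlation) and the p-value of the slope's t-test.
#' Constant y is reported as R^2 = 0 with a warning; constant x is an
#' error (the regression is undefined).
#'
#' @param x,y paired numeric vectors, >= 3 points.
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
regression_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired points")
  if (stats::sd(x) == 0) stop("zero variance in x: regression undefined")
  if (stats::sd(y) == 0) {
    warning("zero variance in y: R^2 reported as 0")
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = stats::cor(x, y)^2,
       p = unname(co["x", "Pr(>|t|)"]))
}

#' Same-odorant versus different-odorant reproducibility contrast
#'
#' Two-sided two-sample t-test comparing R^2 values from the same odorant
#' measured on different days against R^2 values from different odorants
#' measured in the same experiment. High same-odorant and lower
#' cross-odorant correlation is what makes the panel's combinatorial code
#' discriminative.
#'
#' @param same_r2,different_r2 numeric vectors of R^2 values, n >= 2 each.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `t`, `df`, `p`, `mean_same`, `mean_different`.
#' @export
reproducibility_contrast <- function(same_r2, different_r2, var_equal = FALSE) {
  if (length(same_r2) < 2 || length(different_r2) < 2)
    stop("need >= 2 values in each list")
  if (stats::sd(same_r2) == 0 && stats::sd(different_r2) == 0 &&
      mean(same_r2) == mean(different_r2))
    return(list(t = 0, df = NA_real_, p = 1,
                mean_same = mean(same_r2), mean_different = mean(different_r2)))
  tt <- stats::t.test(same_r2, different_r2, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_same = mean(same_r2),
       mean_different = mean(different_r2))
}

#' Fit a Hill dose-response curve
#'
#' Nonlinear least-squares fit of `response = emax * c^h / (c^h + ec50^h)`
#' to a dose series, parameterized on log10(ec50) for stability. Used to
#' check that generative EC50s are recoverable from simulated dose series.
#'
#' @param concentration dose values (mol/L, > 0).
#' @param response response values.
#' @param hill_fixed optionally fix the Hill slope (e.g. 1).
#' @return list with `ec50`, `emax`, `hill`.
#' @export
fit_hill <- function(concentration, response, hill_fixed = NULL) {
  if (length(concentration) != length(response) || length(concentration) < 4)
    stop("need >= 4 paired dose-response points")
  df <- data.frame(c = concentration, r = response)
  start_ec50 <- log10(stats::median(concentration))
  if (is.null(hill_fixed)) {
    fit <- minpack.lm::nlsLM(
      r ~ emax * c^h / (c^h + (10^lec)^h), data = df,
      start = list(emax = max(response), lec = start_ec50, h = 1),
      lower = c(0, -12, 0.2), upper = c(Inf, 0, 5))
    co <- stats::coef(fit)
    list(ec50 = unname(10^co["lec"]), emax = unname(co["emax"]),
         hill = unname(co["h"]))
  } else {
    h <- hill_fixed
    fit <- minpack.lm::nlsLM(
      r ~ emax * c^h / (c^h + (10^lec)^h), data = df,
      start = list(emax = max(response), lec = start_ec50),
      lower = c(0, -12), upper = c(Inf, 0))
    co <- stats::coef(fit)
    list(ec50 = unname(10^co["lec"]), emax = unname(co["emax"]), hill = h)
  }
}
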