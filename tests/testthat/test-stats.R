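# independent brute-force oracles ------------------------------------------

anova_oracle <- function(groups) {
  # explicit sum-of-squares decomposition
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

bh_oracle <- function(p) {
  # literal step-up definition
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$F, 1.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  expect_equal(a$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  # 7 groups x 3 replicates gives df (6, 14)
  g7 <- split(rnorm(21), rep(1:7, each = 3))
  a7 <- one_way_anova(g7)
  expect_equal(c(a7$df_between, a7$df_within), c(6, 14))
  # oracle equivalence on random small instances
  set.seed(11)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2)))
    a <- one_way_anova(g); o <- anova_oracle(g)
    expect_equal(a$F, o$F, tolerance = 1e-6)
    expect_equal(a$p, o$p, tolerance = 1e-6)
  }
  # degenerate all-constant case
  a0 <- one_way_anova(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  expect_error(one_way_anova(list(1, c(1, 2))), "replicates")
})

test_that("f_critical is the upper F quantile", {
  expect_equal(round(f_critical(6, 14, 0.05), 2), 2.85)
  expect_equal(f_critical(1, 1e7, 0.05), stats::qnorm(0.975)^2, tolerance = 1e-3)
  expect_equal(round(f_critical(3, 10, 0.05), 3), 3.708)
  # inverse relation with the F CDF
  for (d in list(c(2, 8), c(6, 14), c(15, 32))) {
    expect_equal(stats::pf(f_critical(d[1], d[2], 0.05), d[1], d[2]),
                 0.95, tolerance = 1e-8)
  }
  expect_error(f_critical(0, 5), "degrees of freedom")
  expect_error(f_critical(2, 5, alpha = 1.2), "alpha")
})

test_that("ANOVA at f_critical rejects at the nominal rate under the null", {
  set.seed(99)
  crit <- f_critical(2, 6, 0.05)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i) {
    g <- split(rnorm(9), rep(1:3, each = 3))
    one_way_anova(g)$F >= crit
  }, logical(1))
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("Tukey HSD matches closed forms and a Monte-Carlo range oracle", {
  # identical groups: adjusted p = 1
  th0 <- tukey_hsd(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(th0$p_adj, 1)
  # two groups: Tukey p equals the pooled two-sample t-test p
  set.seed(5)
  g1 <- rnorm(4); g2 <- rnorm(4, 1)
  th2 <- tukey_hsd(list(a = g1, b = g2))
  expect_equal(th2$p_adj,
               stats::t.test(g1, g2, var.equal = TRUE)$p.value,
               tolerance = 1e-6)
  # 3 groups x 3 reps vs simulated studentized-range null
  g <- list(a = c(1.0, 1.2, 0.9), b = c(1.8, 2.1, 2.0), c = c(1.1, 1.3, 1.0))
  th <- tukey_hsd(g)
  n <- 3; k <- 3; df <- 6
  msw <- mean(vapply(g, stats::var, 1))
  set.seed(123)
  n_mc <- 2e5
  x <- matrix(rnorm(n_mc * k * n), ncol = k * n)
  gm <- sapply(1:k, function(j) rowMeans(x[, ((j - 1) * n + 1):(j * n)]))
  gv <- sapply(1:k, function(j) apply(x[, ((j - 1) * n + 1):(j * n)], 1, var))
  q_null <- (apply(gm, 1, max) - apply(gm, 1, min)) / sqrt(rowMeans(gv) / n)
  for (r in seq_len(nrow(th))) {
    q_obs <- abs(th$diff[r]) / sqrt(msw / n)
    p_mc <- mean(q_null >= q_obs)
    expect_equal(th$p_adj[r], p_mc, tolerance = 0.01)
  }
})

test_that("differential activation counts planted receptor codes", {
  # zero noise: OR1 responds only to odorant A with a large effect
  design <- panel_design(or_ids = c("OR1", "OR2"), control_id = "pCI",
                         odorant_ids = c("A", "B", "C"),
                         conditions = data.frame(odorant = c("A", "B", "C"),
                                                 phase = "vapor",
                                                 concentration = 1e-2),
                         replicates = 3, n_cycles = 10)
  aff <- tiny_affinity(or_id = "OR1", odorant = "A", efficacy = 6, ec50 = 1e-6)
  # small noise so the within-group variance is nonzero
  run <- simulate_plate_run(design, aff, noise = noise_params(0, 0.01, 0),
                            partition_coeffs = stats::setNames(rep(1e-2, 3),
                                                               c("A", "B", "C")),
                            seed = 8)
  dac <- differential_activation_counts(build_response_matrix(run))
  expect_true(all(dac$counts[c("A"), c("B", "C")] >= 1))
  expect_equal(dac$counts["B", "C"], 0)
  expect_true(isSymmetric(dac$counts))
  expect_true(all(dac$counts <= 3))   # bounded by panel size
  # default 7-analog panel at default noise: every pair separated
  run7 <- simulate_panel_day(seed = 21)
  dac7 <- differential_activation_counts(build_response_matrix(run7))
  off <- dac7$counts[upper.tri(dac7$counts)]
  expect_true(all(off >= 1))
  expect_true(isSymmetric(dac7$counts))
})

test_that("all-null panels yield only alpha-level differential counts", {
  design <- default_panel_design(odorants = c("A", "B", "C"))
  run <- simulate_plate_run(design, empty_affinity(),
                            partition_coeffs = stats::setNames(rep(1e-2, 3),
                                                               c("A", "B", "C")),
                            seed = 31)
  dac <- differential_activation_counts(build_response_matrix(run))
  # 32 receptors x 3 pairs, ANOVA-gated Tukey: expect a small count
  expect_lt(sum(dac$counts[upper.tri(dac$counts)]), 0.05 * 32 * 3 * 3)
})

test_that("dunnett_onset finds the first significantly elevated cycle", {
  set.seed(2)
  # flat null: no onset
  null_tc <- data.frame(cycle = rep(1:6, each = 3),
                        value = rnorm(18, 1, 0.05))
  expect_true(is.na(dunnett_onset(null_tc)$onset))
  # step increase at cycle 5
  step_tc <- data.frame(cycle = rep(1:8, each = 3),
                        value = c(rnorm(12, 1, 0.01), rnorm(12, 2, 0.01)))
  res <- dunnett_onset(step_tc)
  expect_equal(res$onset, 5)
  # single-comparison degeneracy: Dunnett p equals the pooled t-test p
  two_tc <- data.frame(cycle = rep(1:2, each = 4),
                       value = c(rnorm(4, 1, 0.2), rnorm(4, 2, 0.2)))
  res2 <- dunnett_onset(two_tc)
  p_t <- stats::t.test(two_tc$value[two_tc$cycle == 2],
                       two_tc$value[two_tc$cycle == 1],
                       var.equal = TRUE)$p.value
  expect_equal(res2$comparisons$p_adj, p_t, tolerance = 1e-3)
  expect_error(dunnett_onset(data.frame(cycle = 1:4, value = rnorm(4))),
               "replicates")
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotonicity: raising any raw p never lowers any adjusted p
  p <- c(0.01, 0.2, 0.04, 0.5)
  for (j in seq_along(p)) {
    p2 <- p; p2[j] <- min(1, p[j] + 0.1)
    expect_true(all(bh_fdr(p2) >= bh_fdr(p) - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ces1d_compare flags planted enhancement and suppression", {
  odorants <- c("EA", "EG")
  pd <- default_or_panel()
  design <- panel_design(or_ids = pd$or_ids, control_id = pd$control_id,
                         odorant_ids = odorants,
                         conditions = data.frame(odorant = "EA",
                                                 phase = "vapor",
                                                 concentration = 1e-2),
                         replicates = 3, n_cycles = 20)
  # OR01 responds weakly to the ester but strongly to its alcohol product;
  # OR02 responds to the ester only, at a dose near its EC50 so that
  # conversion visibly depletes its ligand
  aff <- affinity_model(data.frame(
    or_id = c("OR01", "OR01", "OR02"),
    odorant_id = c("EA", "EG", "EA"),
    ec50 = c(1e-4, 1e-5, 1e-4), efficacy = c(1, 6, 6), hill = 1))
  pc <- stats::setNames(c(1e-2, 1e-2), odorants)
  ces <- ces1d_model(data.frame(substrate = "EA", product = "EG",
                                fraction = 0.5))
  r0 <- simulate_plate_run(design, aff, partition_coeffs = pc, seed = 41)
  r1 <- simulate_plate_run(design, aff, partition_coeffs = pc, ces1d = ces,
                           seed = 42)
  cmp <- ces1d_compare(build_response_matrix(r0), build_response_matrix(r1))
  prod_row <- cmp[cmp$or_id == "OR01", ]
  sub_row <- cmp[cmp$or_id == "OR02", ]
  expect_gt(prod_row$fold, 1)
  expect_true(prod_row$significant)
  expect_lt(sub_row$fold, 1)
  expect_true(sub_row$significant)
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12))
  # identical matrices: defined folds are all 1, nothing significant
  same <- ces1d_compare(build_response_matrix(r0), build_response_matrix(r0))
  expect_equal(same$fold[!same$fold_undefined],
               rep(1, sum(!same$fold_undefined)))
  expect_true(any(!same$fold_undefined))
  expect_false(any(same$significant))
})

test_that("regression_r2 reports OLS fit and squared Pearson", {
  x <- 1:10
  fit <- suppressWarnings(regression_r2(x, 2 * x + 1))  # exact fit is fine here
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  fit2 <- regression_r2(c(1, 2, 3), c(1, 2, 2))
  expect_equal(fit2$r_squared, 0.75)
  expect_equal(fit2$slope, 0.5)
  expect_warning(fit3 <- regression_r2(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_equal(fit3$r_squared, 0)
  expect_error(regression_r2(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_error(regression_r2(1:2, 1:2), "3 paired")
})

test_that("reproducibility_contrast separates same- from cross-odorant R2", {
  same <- c(0.9, 0.95); diff <- c(0.2, 0.3)
  res <- reproducibility_contrast(same, diff, var_equal = TRUE)
  tt <- stats::t.test(same, diff, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)
  expect_lt(res$p, 0.01)
  expect_gt(res$mean_same, res$mean_different)
  # identical lists: p = 1
  expect_equal(reproducibility_contrast(c(0.5, 0.6), c(0.5, 0.6))$p, 1)
  expect_error(reproducibility_contrast(0.9, c(0.1, 0.2)), ">= 2")
})

test_that("generative EC50 is recoverable from a simulated dose series", {
  true_ec50 <- 3e-6
  design <- panel_design(or_ids = "OR1", control_id = "pCI",
                         odorant_ids = "A",
                         conditions = data.frame(odorant = "A",
                                                 phase = "liquid",
                                                 concentration = 10^seq(-8, -3)),
                         replicates = 3, n_cycles = 20)
  aff <- tiny_affinity(ec50 = true_ec50, efficacy = 5)
  run <- simulate_plate_run(design, aff, seed = 77)   # default noise
  s <- build_response_matrix(run)$summary
  s <- s[s$or_id == "OR1", ]
  conc <- as.numeric(sub(".*\\|", "", s$condition))
  fit <- fit_hill(conc, s$mean, hill_fixed = 1)
  expect_gt(fit$ec50, true_ec50 / 2)
  expect_lt(fit$ec50, true_ec50 * 2)
})
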