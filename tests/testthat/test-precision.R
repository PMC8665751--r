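test_that("variance components match the hand-worked duplicate examples", {
  # between-lab spread exactly consumed by within-lab noise: degenerate
  cell <- as_ilc_cell(list(c(1.0, 1.2), c(1.1, 1.3), c(0.9, 1.1)))
  est <- suppressWarnings(anova_components(cell))
  expect_equal(est$s_r, sqrt(0.02))
  expect_equal(est$s_L, 0)
  expect_equal(est$s_R, est$s_r)
  expect_true(est$sL_degenerate)

  # clear between-lab signal
  cell <- as_ilc_cell(list(c(0, 0.2), c(1, 1.2), c(2, 2.2)))
  est <- anova_components(cell)
  expect_equal(est$s_r, sqrt(0.02))
  expect_equal(est$s_L^2, 0.99)
  expect_equal(est$s_R, sqrt(1.01))
  expect_false(est$sL_degenerate)

  # constant cell: everything zero, not flagged degenerate
  cell <- as_ilc_cell(list(c(-24, -24), c(-24, -24)))
  est <- anova_components(cell)
  expect_equal(est$mean, -24)
  expect_equal(est$s_r, 0)
  expect_equal(est$s_R, 0)
  expect_false(est$sL_degenerate)
})

test_that("duplicate shortcut equals the ANOVA repeatability estimate", {
  cell <- as_ilc_cell(list(c(1.0, 1.2), c(1.1, 1.3), c(0.9, 1.1)))
  expect_equal(duplicate_shortcut_sr(cell),
               suppressWarnings(anova_components(cell))$s_r)
  expect_equal(duplicate_shortcut_sr(
    as_ilc_cell(list(c(0, 0), c(1, 1)))), 0)
  # single lab: s_r still defined from its duplicate difference
  one <- as_ilc_cell(list(c(0, 0.2)))
  expect_equal(duplicate_shortcut_sr(one), sqrt(0.04 / 2))
  est1 <- suppressWarnings(anova_components(one))
  expect_equal(est1$s_r, sqrt(0.02))
  expect_false(est1$sL_estimable)
  # non-duplicate design refused
  expect_error(duplicate_shortcut_sr(as_ilc_cell(list(c(0, 1, 2), c(0, 1)))),
               "precondition")
})

test_that("ANOVA path agrees with aov and a two-pass oracle on random cells", {
  set.seed(77)
  for (i in 1:50) {
    cell <- random_duplicate_cell(p = sample(5:20, 1),
                                  s_r = runif(1, 0.05, 0.3),
                                  s_L = runif(1, 0, 0.5))
    est <- suppressWarnings(anova_components(cell))
    orc <- aov_components_oracle(cell)
    tp <- two_pass_components_oracle(cell)
    expect_equal(est$s_r, orc$s_r, tolerance = 1e-10)
    expect_equal(est$s_R, orc$s_R, tolerance = 1e-10)
    expect_equal(est$s_r, tp$s_r, tolerance = 1e-10)
    expect_equal(est$s_R, tp$s_R, tolerance = 1e-10)
    expect_equal(est$s_r, duplicate_shortcut_sr(cell), tolerance = 1e-10)
    expect_equal(est$sL_degenerate, orc$degenerate)
  }
})

test_that("shift invariance and scale equivariance hold", {
  set.seed(5)
  cell <- random_duplicate_cell(p = 10)
  est <- anova_components(cell)
  shifted <- as_ilc_cell(lapply(cell$values, function(v) v + 3))
  est_s <- anova_components(shifted)
  expect_equal(est_s$mean, est$mean + 3)
  expect_equal(est_s$s_r, est$s_r)
  expect_equal(est_s$s_L, est$s_L)
  expect_equal(est_s$s_R, est$s_R)

  scaled <- as_ilc_cell(lapply(cell$values, function(v) v * -2))
  est_c <- anova_components(scaled)
  expect_equal(est_c$mean, -2 * est$mean)
  expect_equal(est_c$s_r, 2 * est$s_r)
  expect_equal(est_c$s_R, 2 * est$s_R)
})

test_that("unbalanced cells reduce correctly and singleton-only cells error", {
  # removing one replicate still gives a consistent two-pass answer
  set.seed(13)
  cell <- random_duplicate_cell(p = 8)
  vals <- cell$values
  vals[[3]] <- vals[[3]][1]
  unb <- as_ilc_cell(vals)
  est <- suppressWarnings(anova_components(unb))
  tp <- two_pass_components_oracle(unb)
  expect_equal(est$s_r, tp$s_r, tolerance = 1e-10)
  expect_equal(est$s_R, tp$s_R, tolerance = 1e-10)
  expect_gte(est$s_R, est$s_r)

  all_single <- as_ilc_cell(list(-24.1, -24.3, -24.2))
  expect_error(anova_components(all_single), "inestimable")
})

test_that("relative SDs use |mean| and are flagged undefined at mean zero", {
  cell <- as_ilc_cell(list(c(-24.20, -24.46), c(-24.5, -24.3), c(-24.2, -24.4)))
  est <- suppressWarnings(anova_components(cell))
  expect_equal(est$rsd_r, 100 * est$s_r / abs(est$mean))
  expect_gt(est$rsd_r, 0)

  zero <- as_ilc_cell(list(c(-1, 1), c(-2, 2), c(2, -2)))
  est0 <- suppressWarnings(anova_components(zero))
  expect_true(est0$rsd_undefined)
  expect_true(is.na(est0$rsd_r))
  expect_gt(est0$s_r, 0)   # absolute values still reported
})

test_that("report rendering reproduces the published rounding convention", {
  est <- structure(list(analyte = "fructose", sample = "A", p_used = 14,
                        n_i = rep(2, 14), mean = -24.33, s_r = 0.13,
                        s_L = sqrt(0.38^2 - 0.13^2), s_R = 0.38,
                        rsd_r = 100 * 0.13 / 24.33, rsd_R = 100 * 0.38 / 24.33,
                        r_limit = 2.80 * 0.13, R_limit = 2.80 * 0.38,
                        sL_degenerate = FALSE, sL_estimable = TRUE,
                        rsd_undefined = FALSE),
                   class = "precision_estimates")
  row <- precision_summary(est)
  expect_equal(row$rsd_R, 1.6)    # published: Relative s_R 1.6 %
  expect_equal(row$rsd_r, 0.5)    # published: Relative s_r 0.5 %
  expect_equal(precision_summary(`class<-`(modifyList(
    unclass(est), list(s_R = 0.43, R_limit = 2.80 * 0.43)),
    "precision_estimates"))$R_limit, 1.20)   # published: R = 1.20
})

test_that("expanded uncertainty is k times the reproducibility SD", {
  u <- expanded_uncertainty(0.38, k = 2)
  expect_equal(u$expanded_U, 0.76)
  expect_equal(expanded_uncertainty(0, k = 2)$expanded_U, 0)
  expect_equal(expanded_uncertainty(0.2, k = 1)$expanded_U, 0.2)
  est <- suppressWarnings(anova_components(
    as_ilc_cell(list(c(0, 0.2), c(1, 1.2), c(2, 2.2)))))
  expect_equal(expanded_uncertainty(est, 2)$expanded_U, 2 * est$s_R)
  expect_error(expanded_uncertainty(0.38, k = 0), "domain error")
})

test_that("evaluate_study screens, estimates and reports per cell", {
  # one variance-outlying lab in one cell only: replace L03's duplicates in
  # (fructose, B) by a huge-difference pair centred on its own mean, so the
  # Cochran test (and only it) must fire there
  spec <- ilc_sim_spec(p = 14, samples = c("A", "B"),
                       mu = c(fructose = -24.3, glucose = -24.5),
                       s_r = 0.10, s_L = 0.27, seed = 33)
  m <- simulate_ilc(spec)$dataset$measurements
  sel <- m$lab == "L03" & m$sample == "B" & m$analyte == "fructose"
  m$delta13c[sel] <- mean(m$delta13c[sel]) + c(-1.5, 1.5)
  rep <- evaluate_study(ilc_dataset(m))
  tb <- rep$table
  hit <- tb[tb$analyte == "fructose" & tb$sample == "B", ]
  expect_equal(hit$outliers_cochran, 1)
  expect_equal(hit$p_used, 13)
  others <- tb[!(tb$analyte == "fructose" & tb$sample == "B"), ]
  expect_true(all(others$p_used >= 13))   # no systematic removals elsewhere

  wide <- report_table(rep, "fructose")
  expect_identical(names(wide), c("parameter", "A", "B"))
  expect_equal(wide[wide$parameter == "Number of laboratories", "B"], 14)
  expect_equal(
    wide[wide$parameter == "Number of laboratories after elimination of outliers", "B"],
    13)
})

test_that("per-cell failures are recorded without aborting the study", {
  m <- rbind(
    data.frame(lab = rep(c("L1", "L2", "L3"), each = 2), sample = "A",
               analyte = "fructose", replicate = rep(1:2, 3),
               delta13c = -24 + rnorm(6, 0, 0.1)),
    data.frame(lab = c("L1", "L2", "L3"), sample = "A",
               analyte = "glucose", replicate = 1,
               delta13c = c(-25, -25.1, -24.9)))   # singletons: s_r inestimable
  rep <- evaluate_study(ilc_dataset(m))
  expect_equal(nrow(rep$table), 1)
  expect_match(rep$failures[["glucose|A"]], "inestimable")
})

test_that("study evaluation honours reduced designs", {
  # only 10 labs report trisaccharides, as in parts of the published study
  sim <- simulate_ilc(ilc_sim_spec(p = 14, samples = "A",
                                   mu = c(trisaccharides = -24,
                                          fructose = -24.3),
                                   s_r = 0.2, s_L = 0.3, seed = 21))
  m <- sim$dataset$measurements
  keep <- !(m$analyte == "trisaccharides" & m$lab %in% sprintf("L%02d", 11:14))
  rep <- evaluate_study(ilc_dataset(m[keep, ]), screen = FALSE)
  expect_equal(rep$table$p_used[rep$table$analyte == "trisaccharides"], 10)
  expect_equal(rep$table$p_used[rep$table$analyte == "fructose"], 14)
})
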