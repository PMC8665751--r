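# duplicate cell whose within-lab variances equal `vars` exactly
cell_with_vars <- function(vars, center = 0) {
  as_ilc_cell(lapply(vars, function(v) center + c(0, sqrt(2 * v))))
}

test_that("Cochran statistic matches hand arithmetic", {
  # equal variances: C = 1/p by symmetry, nothing flagged
  res <- cochran_test(cell_with_vars(c(1, 1, 1, 1)))
  expect_equal(res$statistic, 0.25)
  expect_equal(res$verdict, "none")

  res <- cochran_test(cell_with_vars(c(4, 1, 1, 1)))
  expect_equal(res$statistic, 4 / 7)
  expect_identical(res$suspect_lab, "L01")
  expect_false(res$masking_warning)

  # two equally inflated labs mask each other
  res <- cochran_test(cell_with_vars(c(8, 8, 1, 1, 1)))
  expect_equal(res$statistic, 8 / 19)
  expect_true(res$masking_warning)
  expect_equal(res$verdict, "none")   # kept for further evaluation
})

test_that("Cochran statistic lies in (1/p, 1] and hits 1/p iff variances equal", {
  set.seed(31)
  for (i in 1:20) {
    p <- sample(3:12, 1)
    res <- cochran_test(cell_with_vars(runif(p, 0.1, 4)))
    expect_gt(res$statistic, 1 / p)
    expect_lte(res$statistic, 1)
  }
})

test_that("Cochran preconditions and critical-value domain are enforced", {
  cell <- as_ilc_cell(list(c(0, 1), c(0, 2), c(0.5)))
  expect_error(cochran_test(cell), "precondition error.*L03")
  expect_error(cochran_critical(2, 2, 0.05), "p >= 3")
  expect_error(cochran_critical(14, 1, 0.05), "n >= 2")
  expect_error(cochran_critical(14, 2, 1.2), "alpha")
})

test_that("Cochran critical values: closed form tracks Monte Carlo; alpha -> 1 approaches 1/p", {
  mc <- cochran_critical(14, 2, 0.05, method = "mc", n_mc = 5e5)
  closed <- cochran_critical(14, 2, 0.05)
  expect_lt(abs(mc - closed), 0.005)
  # critical value decreases toward the equal-share floor 1/p as alpha -> 1
  crits <- vapply(c(0.5, 0.95, 0.999), function(a)
    cochran_critical(4, 2, a, method = "mc", n_mc = 2e5), numeric(1))
  expect_true(all(diff(crits) < 0))
  expect_gt(crits[3], 1 / 4)
  expect_lt(crits[3], 1 / 4 + 0.05)
})

test_that("single Grubbs matches hand arithmetic and flags the right lab", {
  res <- grubbs_single(c(0, 0, 0, 10))
  expect_equal(res$statistic, 1.5)       # mean 2.5, sd 5
  expect_identical(res$suspect_labs, "L04")
  expect_identical(res$side, "high")

  res <- grubbs_single(c(-1, 0, 1))
  expect_equal(res$statistic, 1)
  expect_equal(res$verdict, "none")

  expect_error(grubbs_single(c(2, 2, 2, 2)), "degenerate-input")
  expect_error(grubbs_single(c(1, 2)), "p >= 3")
})

test_that("double Grubbs detects an outlying pair that masks the single test", {
  x <- c(rep(0, 10), 10, 10)
  res <- grubbs_double(x, alpha_remove = 0.01)
  expect_identical(res$side, "pair_high")
  expect_lt(res$statistic, 0.01)         # reduced SS ratio near zero
  expect_equal(res$verdict, "outlier")
  expect_setequal(res$suspect_labs, c("L11", "L12"))

  res_lin <- grubbs_double(1:10)
  expect_equal(res_lin$verdict, "none")

  expect_error(grubbs_double(1:4), "p >= 5")
})

test_that("screening removes a strongly biased laboratory and records it", {
  set.seed(7)
  cell <- random_duplicate_cell(p = 14, s_r = 0.1, s_L = 0.3)
  shifted <- cell$values
  shifted[["L05"]] <- shifted[["L05"]] + 10 * 0.3   # 10 x s_L bias shift
  cell2 <- as_ilc_cell(shifted)
  scr <- screen_cell(cell2)
  expect_true("L05" %in% scr$removed_labs)
  rec <- scr$records
  removed <- rec[rec$action == "removed", ]
  expect_true("L05" %in% removed$lab)
  expect_true(all(removed$test %in% c("grubbs_single", "grubbs_double")))
  expect_true(all(removed$statistic > removed$critical |
                    removed$test == "grubbs_double"))
})

test_that("screening is idempotent and its audit trail replays exactly", {
  set.seed(12)
  for (i in 1:5) {
    cell <- random_duplicate_cell(p = 14)
    cell$values[[sample(14, 1)]] <- cell$values[[1]] + rnorm(2, 5, 0.1)
    cell <- as_ilc_cell(cell$values)
    scr <- screen_cell(cell)
    # replay
    expect_identical(replay_screening(cell, scr$records), scr$cell)
    # idempotence
    scr2 <- screen_cell(scr$cell)
    expect_length(scr2$removed_labs, 0)
  }
})

test_that("a straggler is flagged but never removed", {
  # scan for a configuration significant at 5% but not 1%
  base <- c(-0.5, -0.3, -0.1, 0, 0.1, 0.2, 0.3, 0.4, 0.5)
  found <- FALSE
  for (x in seq(1.0, 3.0, by = 0.05)) {
    res <- grubbs_single(c(base, x))
    if (res$verdict == "straggler") {
      found <- TRUE
      scr <- screen_cell(as_ilc_cell(lapply(c(base, x), function(m) m + c(-0.01, 0.01))))
      expect_length(scr$removed_labs, 0)
      flagged <- scr$records[scr$records$action == "flagged", ]
      expect_true(nrow(flagged) >= 1)
      break
    }
  }
  expect_true(found)
})

test_that("removal is capped at the policy fraction of laboratories", {
  # 9 labs tightly grouped + 3 extreme singles: cap 2/9 allows at most 2 removals
  set.seed(9)
  vals <- c(lapply(rnorm(9, 0, 0.05), function(m) m + c(-0.01, 0.01)),
            lapply(c(8, 12, 16), function(m) m + c(-0.01, 0.01)))
  scr <- screen_cell(as_ilc_cell(vals))
  expect_lte(length(scr$removed_labs), floor(2 / 9 * 12))
  expect_true(any(scr$records$action == "stopped") ||
                length(scr$removed_labs) < floor(2 / 9 * 12))
})

test_that("clean cells survive screening untouched almost always", {
  set.seed(20)
  n_reps <- 400
  untouched <- 0
  for (i in seq_len(n_reps)) {
    scr <- screen_cell(random_duplicate_cell(p = 14, s_r = 0.1, s_L = 0.3))
    if (length(scr$removed_labs) == 0) untouched <- untouched + 1
  }
  # family of 1%-level tests: expected no-removal rate ~97%
  expect_gte(untouched / n_reps, 0.95)
})
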