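#' Screening policy for iterative outlier removal
#'
#' Classical two-level convention: values significant at `alpha_flag` but not
#' `alpha_remove` are "stragglers" (flagged, kept), values significant at
#' `alpha_remove` are outliers (the whole laboratory is removed from the
#' cell).  Tests run in `test_order`; after each removal the sequence
#' restarts, so the double Grubbs test is only reached when the Cochran and
#' single Grubbs tests find nothing.  Removal stops when it would exceed
#' `max_removed_fraction` of the cell's initial laboratories.
#'
#' @param alpha_remove removal (outlier) level, default 0.01.
#' @param alpha_flag flagging (straggler) level, default 0.05.
#' @param max_removed_fraction cap on the fraction of labs removed per cell,
#'   default 2/9.
#' @param test_order character vector ordering of
#'   `"cochran"`, `"grubbs_single"`, `"grubbs_double"`.
#' @param iterate restart the test sequence after each removal (default TRUE).
#' @return object of class `screening_policy`.
#' @export
screening_policy <- function(alpha_remove = 0.01, alpha_flag = 0.05,
                             max_removed_fraction = 2 / 9,
                             test_order = c("cochran", "grubbs_single",
                                            "grubbs_double"),
                             iterate = TRUE) {
  stopifnot(is.numeric(alpha_remove), is.numeric(alpha_flag))
  if (!(alpha_remove > 0 && alpha_remove <= alpha_flag && alpha_flag < 1))
    stop("require 0 < alpha_remove <= alpha_flag < 1", call. = FALSE)
  if (!(max_removed_fraction >= 0 && max_removed_fraction < 1))
    stop("require 0 <= max_removed_fraction < 1", call. = FALSE)
  test_order <- match.arg(test_order,
                          c("cochran", "grubbs_single", "grubbs_double"),
                          several.ok = TRUE)
  structure(list(alpha_remove = alpha_remove, alpha_flag = alpha_flag,
                 max_removed_fraction = max_removed_fraction,
                 test_order = test_order, iterate = isTRUE(iterate)),
            class = "screening_policy")
}

verdict_from <- function(exceed_remove, exceed_flag) {
  if (exceed_remove) "outlier" else if (exceed_flag) "straggler" else "none"
}

#' Cochran test for an outlying within-laboratory variance
#'
#' C = largest within-laboratory variance / sum of within-laboratory
#' variances.  A masking warning is raised when the second-largest variance
#' is at least 80% of the largest: two similarly inflated laboratories can
#' each hide the other from this single-outlier test.
#'
#' @param cell an `ilc_cell` (every laboratory needs >= 2 replicates and the
#'   cell >= 3 laboratories).
#' @param alpha_remove,alpha_flag outlier and straggler levels.
#' @return list of class `cochran_result`: `statistic`, `suspect_lab`,
#'   `critical_remove`, `critical_flag`, `verdict`
#'   (`"none"`/`"straggler"`/`"outlier"`), `masking_warning`.
#' @export
#' @examples
#' cell <- as_ilc_cell(list(c(0, 2), c(0, 1), c(1, 2), c(0.5, 1.5)))
#' cochran_test(cell)
cochran_test <- function(cell, alpha_remove = 0.01, alpha_flag = 0.05) {
  stopifnot(inherits(cell, "ilc_cell"))
  if (cell$p < 3)
    stop("precondition error: Cochran test needs p >= 3 laboratories",
         call. = FALSE)
  short <- cell$labs[cell$n_i < 2]
  if (length(short))
    stop("precondition error: laboratory ", short[1],
         " has fewer than 2 replicates", call. = FALSE)
  v <- vapply(cell$values, var, numeric(1))
  if (all(v == 0))
    stop("degenerate-input error: all within-laboratory variances are zero",
         call. = FALSE)
  i_max <- which.max(v)
  C <- v[i_max] / sum(v)
  # critical value uses the typical replicate count of the cell
  n_eff <- max(2L, as.integer(round(mean(cell$n_i))))
  crit_r <- cochran_critical(cell$p, n_eff, alpha_remove)
  crit_f <- cochran_critical(cell$p, n_eff, alpha_flag)
  second <- if (cell$p > 1) max(v[-i_max]) else 0
  structure(list(statistic = unname(C),
                 suspect_lab = cell$labs[i_max],
                 critical_remove = crit_r, critical_flag = crit_f,
                 verdict = verdict_from(C > crit_r, C > crit_f),
                 masking_warning = second >= 0.8 * v[i_max]),
            class = "cochran_result")
}

#' Single Grubbs test for one outlying laboratory mean
#'
#' Two-sided: tests the more extreme of the lowest and highest value with
#' G = max(|x_(1) - mean|, |x_(p) - mean|) / sd.
#'
#' @param x numeric vector of laboratory means (or an `ilc_cell`, whose
#'   per-laboratory replicate means are used); p >= 3, sd > 0.
#' @param alpha_remove,alpha_flag outlier and straggler levels.
#' @return list of class `grubbs_result` with `statistic`, `suspect_labs`,
#'   `side` (`"low"`/`"high"`), `critical_remove`, `critical_flag`, `verdict`.
#' @export
#' @examples
#' grubbs_single(c(0, 0, 0, 10))
grubbs_single <- function(x, alpha_remove = 0.01, alpha_flag = 0.05) {
  labs <- NULL
  if (inherits(x, "ilc_cell")) {
    labs <- x$labs
    x <- vapply(x$values, mean, numeric(1))
  }
  if (is.null(labs))
    labs <- names(x) %||% sprintf("L%02d", seq_along(x))
  x <- as.numeric(x)
  p <- length(x)
  if (p < 3)
    stop("precondition error: single Grubbs test needs p >= 3", call. = FALSE)
  s <- sd(x)
  if (s == 0)
    stop("degenerate-input error: zero standard deviation of laboratory means",
         call. = FALSE)
  m <- mean(x)
  i_lo <- which.min(x); i_hi <- which.max(x)
  g_lo <- (m - x[i_lo]) / s; g_hi <- (x[i_hi] - m) / s
  if (g_hi >= g_lo) { G <- g_hi; side <- "high"; suspect <- labs[i_hi] }
  else             { G <- g_lo; side <- "low";  suspect <- labs[i_lo] }
  crit_r <- grubbs_single_critical(p, alpha_remove)
  crit_f <- grubbs_single_critical(p, alpha_flag)
  structure(list(statistic = unname(G), suspect_labs = suspect, side = side,
                 critical_remove = crit_r, critical_flag = crit_f,
                 verdict = verdict_from(G > crit_r, G > crit_f)),
            class = "grubbs_result")
}

#' Double Grubbs test for a pair of outlying laboratory means
#'
#' Tests the two lowest and the two highest values jointly through the ratio
#' of the sum of squares about the mean after removing the pair to the full
#' sum of squares; a small ratio flags the pair.  Designed for the masking
#' situation where two similar extremes hide each other from the single test.
#'
#' @inheritParams grubbs_single
#' @param n_mc Monte-Carlo draws behind the critical-value tabulation.
#' @return list of class `grubbs_result`; `statistic` is the smaller of the
#'   two side ratios, `side` is `"pair_low"` or `"pair_high"`, and verdicts
#'   fire when the statistic falls BELOW the critical value.
#' @export
grubbs_double <- function(x, alpha_remove = 0.01, alpha_flag = 0.05,
                          n_mc = 5e5) {
  labs <- NULL
  if (inherits(x, "ilc_cell")) {
    labs <- x$labs
    x <- vapply(x$values, mean, numeric(1))
  }
  if (is.null(labs))
    labs <- names(x) %||% sprintf("L%02d", seq_along(x))
  x <- as.numeric(x)
  p <- length(x)
  if (p < 5)
    stop("precondition error: double Grubbs test needs p >= 5", call. = FALSE)
  ss <- function(v) sum((v - mean(v))^2)
  ss0 <- ss(x)
  if (ss0 == 0)
    stop("degenerate-input error: zero spread of laboratory means", call. = FALSE)
  o <- order(x)
  r_lo <- ss(x[o][-(1:2)]) / ss0
  r_hi <- ss(x[o][-((p - 1):p)]) / ss0
  if (r_lo <= r_hi) {
    D <- r_lo; side <- "pair_low"; suspects <- labs[o][1:2]
  } else {
    D <- r_hi; side <- "pair_high"; suspects <- labs[o][(p - 1):p]
  }
  crit_r <- grubbs_double_critical(p, alpha_remove, n_mc)
  crit_f <- grubbs_double_critical(p, alpha_flag, n_mc)
  structure(list(statistic = unname(D), suspect_labs = suspects, side = side,
                 critical_remove = crit_r, critical_flag = crit_f,
                 verdict = verdict_from(D < crit_r, D < crit_f)),
            class = "grubbs_result")
}

empty_records <- function() {
  data.frame(analyte = character(), sample = character(),
             iteration = integer(), test = character(), lab = character(),
             statistic = numeric(), critical = numeric(), alpha = numeric(),
             action = character(), note = character(),
             stringsAsFactors = FALSE)
}

record_row <- function(cell, iteration, test, lab, statistic, critical,
                       alpha, action, note = "") {
  data.frame(analyte = cell$analyte, sample = cell$sample,
             iteration = as.integer(iteration), test = test, lab = lab,
             statistic = statistic, critical = critical, alpha = alpha,
             action = action, note = note, stringsAsFactors = FALSE)
}

drop_labs <- function(cell, labs) {
  keep <- setdiff(cell$labs, labs)
  if (!length(keep))
    stop("screening cannot remove every laboratory from a cell", call. = FALSE)
  new_cell(cell$analyte, cell$sample, cell$values[keep])
}

run_one_test <- function(cell, test, policy, n_mc = 5e5) {
  switch(test,
    cochran = {
      if (cell$p < 3 || any(cell$n_i < 2)) return(NULL)
      v <- vapply(cell$values, var, numeric(1))
      if (all(v == 0)) return(NULL)
      cochran_test(cell, policy$alpha_remove, policy$alpha_flag)
    },
    grubbs_single = {
      if (cell$p < 3) return(NULL)
      means <- vapply(cell$values, mean, numeric(1))
      if (sd(means) == 0) return(NULL)
      grubbs_single(cell, policy$alpha_remove, policy$alpha_flag)
    },
    grubbs_double = {
      if (cell$p < 5) return(NULL)
      means <- vapply(cell$values, mean, numeric(1))
      if (sd(means) == 0) return(NULL)
      grubbs_double(cell, policy$alpha_remove, policy$alpha_flag, n_mc)
    })
}

result_suspects <- function(res) {
  if (inherits(res, "cochran_result")) res$suspect_lab else res$suspect_labs
}

#' Iteratively screen a cell for outlying laboratories
#'
#' Applies the policy's tests in order.  A laboratory (or pair) significant
#' at the removal level is removed as a whole and the sequence restarts; a
#' straggler (significant only at the flagging level) is recorded but kept.
#' Screening ends when a full pass removes nothing, when test preconditions
#' fail (recorded as skips), or when further removal would exceed the
#' policy's cap on the fraction of laboratories removed.  Every event goes
#' into an append-only audit trail from which [replay_screening()] can
#' rebuild the cleaned cell exactly.
#'
#' @param cell an `ilc_cell`.
#' @param policy a [screening_policy()].
#' @return list of class `ilc_screening`: `cell_raw`, `cell` (cleaned),
#'   `records` (audit data.frame), `removed_labs`, `masking_warning`.
#' @export
screen_cell <- function(cell, policy = screening_policy()) {
  stopifnot(inherits(cell, "ilc_cell"))
  raw <- cell
  records <- empty_records()
  masking <- FALSE
  p0 <- cell$p
  max_remove <- floor(policy$max_removed_fraction * p0)
  iteration <- 0L

  repeat {
    iteration <- iteration + 1L
    removed_this_pass <- FALSE
    for (test in policy$test_order) {
      res <- run_one_test(cell, test, policy)
      if (is.null(res)) {
        records <- rbind(records, record_row(
          cell, iteration, test, NA_character_, NA_real_, NA_real_, NA_real_,
          "skipped", "precondition not met"))
        next
      }
      if (inherits(res, "cochran_result") && res$masking_warning) {
        masking <- TRUE
        records <- rbind(records, record_row(
          cell, iteration, test, res$suspect_lab, res$statistic,
          res$critical_remove, policy$alpha_remove, "warning",
          "possible masking: second-largest within-lab variance >= 0.8 x largest"))
      }
      suspects <- result_suspects(res)
      crit_used <- if (res$verdict == "outlier") res$critical_remove
                   else res$critical_flag
      if (res$verdict == "outlier") {
        n_removed <- p0 - cell$p
        if (n_removed + length(suspects) > max_remove) {
          records <- rbind(records, record_row(
            cell, iteration, test, paste(suspects, collapse = "+"),
            res$statistic, res$critical_remove, policy$alpha_remove,
            "stopped", sprintf("removal cap %.3f of %d labs reached",
                               policy$max_removed_fraction, p0)))
          return(finish_screening(raw, cell, records, masking))
        }
        for (lab in suspects)
          records <- rbind(records, record_row(
            cell, iteration, test, lab, res$statistic, res$critical_remove,
            policy$alpha_remove, "removed"))
        cell <- drop_labs(cell, suspects)
        removed_this_pass <- TRUE
        if (policy$iterate) break     # restart the full sequence
      } else if (res$verdict == "straggler") {
        for (lab in suspects)
          records <- rbind(records, record_row(
            cell, iteration, test, lab, res$statistic, res$critical_flag,
            policy$alpha_flag, "flagged"))
      }
    }
    if (!removed_this_pass || !policy$iterate) break
  }
  finish_screening(raw, cell, records, masking)
}

finish_screening <- function(raw, cell, records, masking) {
  structure(list(cell_raw = raw, cell = cell, records = records,
                 removed_labs = setdiff(raw$labs, cell$labs),
                 masking_warning = masking),
            class = "ilc_screening")
}

#' @export
print.ilc_screening <- function(x, ...) {
  cat("Screening of (", x$cell_raw$analyte, ", ", x$cell_raw$sample, "): ",
      x$cell_raw$p, " -> ", x$cell$p, " labs",
      if (length(x$removed_labs))
        paste0(" (removed: ", paste(x$removed_labs, collapse = ", "), ")"),
      if (x$masking_warning) " [masking warning]", "\n", sep = "")
  invisible(x)
}

#' Replay an audit trail against a raw cell
#'
#' Applies only the `action == "removed"` rows of a screening audit trail to
#' the raw cell; the result reproduces the cleaned cell exactly.
#'
#' @param cell the raw `ilc_cell` that was screened.
#' @param records the `records` data.frame from [screen_cell()].
#' @return the cleaned `ilc_cell`.
#' @export
replay_screening <- function(cell, records) {
  stopifnot(inherits(cell, "ilc_cell"))
  removed <- records$lab[records$action == "removed"]
  if (!length(removed)) return(cell)
  drop_labs(cell, removed)
}
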