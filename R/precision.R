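#' One-way random-effects variance components for a cell
#'
#' The classical interlaboratory precision decomposition: measurements in a
#' cell follow y_ij = m + B_i + e_ij with laboratory effect B_i (variance
#' s_L^2) and replicate error e_ij (variance s_r^2).  The pooled within-
#' laboratory variance estimates s_r^2; the between-laboratory mean square
#' MSB, on an effective replicate number n_bar (which reduces to n for
#' balanced cells), gives s_L^2 = (MSB - s_r^2)/n_bar.  A non-positive
#' estimate is truncated: s_L = 0, s_R = s_r and the result is marked
#' degenerate — between-laboratory reproducibility is then understated and a
#' warning is emitted.  Reproducibility is s_R = sqrt(s_r^2 + s_L^2), the
#' repeatability and reproducibility limits are r = 2.80 s_r and
#' R = 2.80 s_R, and relative SDs are 100 s / |mean| in percent.
#'
#' @param cell an `ilc_cell` with p >= 1 laboratories; estimating s_L needs
#'   p >= 2 and estimating s_r needs at least one laboratory with >= 2
#'   replicates.
#' @return object of class `precision_estimates` with fields `p_used`, `n_i`,
#'   `mean`, `s_r`, `s_L`, `s_R`, `rsd_r`, `rsd_R`, `r_limit`, `R_limit`,
#'   `sL_degenerate`, `sL_estimable`, `rsd_undefined`.
#' @export
#' @examples
#' cell <- as_ilc_cell(list(c(0, 0.2), c(1, 1.2), c(2, 2.2)))
#' anova_components(cell)
anova_components <- function(cell) {
  stopifnot(inherits(cell, "ilc_cell"))
  n_i <- cell$n_i
  p <- cell$p
  N <- sum(n_i)
  if (all(n_i < 2))
    stop("s_r inestimable: every laboratory reported a single replicate",
         call. = FALSE)
  ybar_i <- vapply(cell$values, mean, numeric(1))
  grand <- sum(n_i * ybar_i) / N
  ss_within <- sum(vapply(cell$values, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  df_within <- sum(n_i - 1)
  s_r2 <- ss_within / df_within

  sL_estimable <- p >= 2
  sL_degenerate <- FALSE
  if (sL_estimable) {
    msb <- sum(n_i * (ybar_i - grand)^2) / (p - 1)
    n_bar <- (N - sum(n_i^2) / N) / (p - 1)
    s_L2 <- (msb - s_r2) / n_bar
    # between-lab mean square <= within mean square (up to representation
    # noise): truncate and flag — unless the cell is perfectly constant
    if (msb <= s_r2 * (1 + 1e-9)) {
      sL_degenerate <- !(msb == 0 && s_r2 == 0)
      s_L2 <- 0
    }
  } else {
    s_L2 <- 0
    sL_degenerate <- TRUE
  }
  if (sL_degenerate)
    warning("between-laboratory component not estimable in (",
            cell$analyte, ", ", cell$sample,
            "): s_R set equal to s_r; reproducibility is understated",
            call. = FALSE)
  s_r <- sqrt(s_r2)
  s_L <- sqrt(s_L2)
  s_R <- sqrt(s_r2 + s_L2)
  rsd_undefined <- grand == 0
  structure(list(analyte = cell$analyte, sample = cell$sample,
                 p_used = p, n_i = n_i, mean = grand,
                 s_r = s_r, s_L = s_L, s_R = s_R,
                 rsd_r = if (rsd_undefined) NA_real_ else 100 * s_r / abs(grand),
                 rsd_R = if (rsd_undefined) NA_real_ else 100 * s_R / abs(grand),
                 r_limit = 2.80 * s_r, R_limit = 2.80 * s_R,
                 sL_degenerate = sL_degenerate,
                 sL_estimable = sL_estimable,
                 rsd_undefined = rsd_undefined),
            class = "precision_estimates")
}

#' @export
print.precision_estimates <- function(x, digits = 4, ...) {
  cat("Precision estimates (", x$analyte, ", sample ", x$sample, ")\n",
      sep = "")
  cat(sprintf("  p = %d labs | mean = %.*f permil\n", x$p_used, digits, x$mean))
  cat(sprintf("  s_r = %.*f  s_L = %.*f  s_R = %.*f%s\n",
              digits, x$s_r, digits, x$s_L, digits, x$s_R,
              if (x$sL_degenerate) "  [s_L not estimable: s_R = s_r]" else ""))
  cat(sprintf("  RSD_r = %.2f%%  RSD_R = %.2f%%  r = %.*f  R = %.*f\n",
              x$rsd_r, x$rsd_R, digits, x$r_limit, digits, x$R_limit))
  invisible(x)
}

#' Repeatability SD from duplicate differences
#'
#' For the duplicate design (exactly two replicates per laboratory) the
#' pooled within-laboratory variance reduces to s_r^2 = sum(d_i^2) / (2 p)
#' over the per-laboratory duplicate differences d_i.  Must agree with the
#' ANOVA estimate to numerical round-off.
#'
#' @param cell an `ilc_cell` in which every laboratory has exactly 2
#'   replicates.
#' @return the repeatability standard deviation s_r.
#' @export
duplicate_shortcut_sr <- function(cell) {
  stopifnot(inherits(cell, "ilc_cell"))
  if (!all(cell$n_i == 2))
    stop("precondition error: duplicate shortcut needs exactly 2 replicates per laboratory",
         call. = FALSE)
  d <- vapply(cell$values, function(v) v[1] - v[2], numeric(1))
  sqrt(sum(d^2) / (2 * cell$p))
}

#' Render precision estimates as a report row
#'
#' Applies the report rounding convention (half-up, as in printed precision
#' tables): mean and SDs to 2 decimals, relative SDs to 1 decimal, limits to
#' 2 decimals by default.  Rounding happens only here, at render time; the
#' underlying estimates keep full precision.
#'
#' @param est a `precision_estimates` object.
#' @param rounding named list of decimal places: `mean`, `sd`, `rsd`, `limit`.
#' @return one-row data.frame in report layout.
#' @export
precision_summary <- function(est,
                              rounding = list(mean = 2, sd = 2, rsd = 1,
                                              limit = 2)) {
  stopifnot(inherits(est, "precision_estimates"))
  r <- function(x, d) if (is.na(x)) NA_real_ else round_half_up(x, d)
  data.frame(analyte = est$analyte, sample = est$sample,
             p_used = est$p_used,
             mean = r(est$mean, rounding$mean),
             s_R = r(est$s_R, rounding$sd),
             s_r = r(est$s_r, rounding$sd),
             rsd_R = r(est$rsd_R, rounding$rsd),
             rsd_r = r(est$rsd_r, rounding$rsd),
             R_limit = r(est$R_limit, rounding$limit),
             r_limit = r(est$r_limit, rounding$limit),
             sL_degenerate = est$sL_degenerate,
             stringsAsFactors = FALSE)
}

#' Measurement uncertainty from the reproducibility SD
#'
#' Uses the interlaboratory reproducibility standard deviation as the
#' standard measurement uncertainty of a single result and expands it with a
#' coverage factor (k = 2 for ~95% coverage).
#'
#' @param est a `precision_estimates` object, or a numeric s_R value.
#' @param k coverage factor (> 0).
#' @return list of class `uncertainty_estimate`: `standard_u`, `coverage_k`,
#'   `expanded_U` (all in per mil).
#' @export
#' @examples
#' expanded_uncertainty(0.38, k = 2)   # U = 0.76 permil
expanded_uncertainty <- function(est, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("domain error: coverage factor k must be positive", call. = FALSE)
  s_R <- if (inherits(est, "precision_estimates")) est$s_R else as.numeric(est)
  if (!is.finite(s_R) || s_R < 0)
    stop("domain error: s_R must be a finite non-negative value", call. = FALSE)
  structure(list(standard_u = s_R, coverage_k = k, expanded_U = k * s_R),
            class = "uncertainty_estimate")
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat(sprintf("u = s_R = %.4f permil; U = %g x u = %.4f permil\n",
              x$standard_u, x$coverage_k, x$expanded_U))
  invisible(x)
}

#' Evaluate a full ILC study
#'
#' For every non-empty (analyte, sample) cell: outlier screening per the
#' policy, variance-component estimation on the cleaned cell, and a report
#' row.  Per-cell failures are recorded in the report and never abort the
#' other cells.
#'
#' @param ds an [ilc_dataset()].
#' @param policy a [screening_policy()]; `screen = FALSE` skips screening
#'   entirely (used e.g. for parameter-recovery simulations).
#' @param screen logical, apply outlier screening (default TRUE).
#' @return object of class `ilc_study_report`: `table` (long data.frame of
#'   rendered rows plus lab counts and per-test outlier counts), `estimates`
#'   (list of `precision_estimates`), `screenings` (list of `ilc_screening`),
#'   `audit` (combined audit data.frame), `failures`, `policy`.
#' @export
evaluate_study <- function(ds, policy = screening_policy(), screen = TRUE) {
  stopifnot(inherits(ds, "ilc_dataset"))
  cells <- list_cells(ds)
  rows <- list(); estimates <- list(); screenings <- list()
  audit <- empty_records(); failures <- list()
  for (i in seq_len(nrow(cells))) {
    an <- cells$analyte[i]; sa <- cells$sample[i]
    key <- paste(an, sa, sep = "|")
    res <- tryCatch({
      cell <- extract_cell(ds, an, sa)
      scr <- if (screen) screen_cell(cell, policy)
             else finish_screening(cell, cell, empty_records(), FALSE)
      est <- suppressWarnings(anova_components(scr$cell))
      row <- precision_summary(est)
      row$p_initial <- cell$p
      rec <- scr$records
      removed <- rec[rec$action == "removed", , drop = FALSE]
      row$outliers_cochran <- sum(removed$test == "cochran")
      row$outliers_grubbs <- sum(removed$test == "grubbs_single")
      row$outliers_double_grubbs <- sum(removed$test == "grubbs_double")
      row$masking_warning <- scr$masking_warning
      list(row = row, est = est, scr = scr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    rows[[key]] <- res$row
    estimates[[key]] <- res$est
    screenings[[key]] <- res$scr
    audit <- rbind(audit, res$scr$records)
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(table)) rownames(table) <- NULL
  structure(list(table = table, estimates = estimates,
                 screenings = screenings, audit = audit,
                 failures = failures, policy = policy,
                 metadata = ds$metadata,
                 design_n = ds$design_n),
            class = "ilc_study_report")
}

#' @export
print.ilc_study_report <- function(x, ...) {
  cat("ILC study report: ", if (is.null(x$table)) 0 else nrow(x$table),
      " cells evaluated, ", length(x$failures), " failed\n", sep = "")
  if (!is.null(x$table)) {
    for (an in unique(x$table$analyte)) {
      cat("\n== ", an, " ==\n", sep = "")
      print(report_table(x, an))
    }
  }
  if (length(x$failures)) {
    cat("\nFailed cells:\n")
    for (k in names(x$failures))
      cat("  ", gsub("\\|", ", ", k), ": ", x$failures[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' Per-analyte precision table in the published layout
#'
#' One column per sample, one row per reported parameter: laboratory counts
#' before and after elimination, per-test outlier counts, mean, s_R, s_r,
#' relative SDs, and the 2.80-factor reproducibility and repeatability
#' limits.
#'
#' @param report an `ilc_study_report`.
#' @param analyte which analyte's table to render.
#' @return data.frame with a `parameter` column and one column per sample.
#' @export
report_table <- function(report, analyte) {
  stopifnot(inherits(report, "ilc_study_report"))
  tb <- report$table[report$table$analyte == analyte, , drop = FALSE]
  if (!nrow(tb))
    stop("lookup error: no evaluated cells for analyte '", analyte, "'",
         call. = FALSE)
  tb <- tb[order(tb$sample), , drop = FALSE]
  params <- c("Number of laboratories",
              "Number of laboratories after elimination of outliers",
              "Outliers (Cochran test)", "Outliers (Grubbs test)",
              "Outliers (Double Grubbs test)",
              "Mean (delta13C permil)",
              "Reproducibility standard deviation (s_R)",
              "Repeatability standard deviation (s_r)",
              "Relative s_R (%)", "Relative s_r (%)",
              "Reproducibility, R (2.80 * s_R)",
              "Repeatability, r (2.80 * s_r)")
  cols <- lapply(seq_len(nrow(tb)), function(i) with(tb[i, ], c(
    p_initial, p_used, outliers_cochran, outliers_grubbs,
    outliers_double_grubbs, mean, s_R, s_r, rsd_R, rsd_r, R_limit, r_limit)))
  out <- data.frame(parameter = params, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tb))) out[[tb$sample[i]]] <- cols[[i]]
  out
}

#' Write a study report to disk
#'
#' Writes one TSV per analyte in the published table layout, a full-precision
#' machine-readable JSON report (versioned schema) and a JSON-lines audit
#' log of every screening event.
#'
#' @param report an `ilc_study_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ilc_study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (an in unique(report$table$analyte)) {
    p <- file.path(dir, paste0("precision_", gsub("[^A-Za-z0-9]+", "_", an),
                               ".tsv"))
    utils::write.table(report_table(report, an), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  full <- lapply(report$estimates, function(e)
    e[c("analyte", "sample", "p_used", "mean", "s_r", "s_L", "s_R",
        "rsd_r", "rsd_R", "r_limit", "R_limit", "sL_degenerate")])
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(report_version = 1L,
         policy = unclass(report$policy),
         design_n = report$design_n,
         cells = unname(full),
         failures = report$failures,
         rendered = report$table),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, json_path)
  audit_path <- file.path(dir, "audit.jsonl")
  con <- file(audit_path, "w")
  if (nrow(report$audit))
    for (i in seq_len(nrow(report$audit)))
      writeLines(jsonlite::toJSON(as.list(report$audit[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  close(con)
  invisible(c(paths, audit_path))
}
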