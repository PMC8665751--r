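#' Published precision summary of the honey-saccharide ILC
#'
#' The per-analyte, per-sample precision summary of a published 14-laboratory
#' interlaboratory comparison of LC-IRMS delta-13C determination in six honey
#' samples (A-F): laboratory counts before/after outlier elimination,
#' per-test outlier counts, the mean delta-13C, the reproducibility and
#' repeatability standard deviations, their relative values in percent, and
#' the 2.80-factor reproducibility and repeatability limits — all as printed
#' (means and SDs to 2 decimals, relative SDs to 1 decimal with one 2-decimal
#' entry kept verbatim).  Raw per-laboratory data were not published;
#' the oligosaccharide fraction was reported by the participants but has no
#' published precision table and is therefore absent here.
#'
#' @return data.frame with one row per (analyte, sample): columns `analyte`,
#'   `sample`, `p`, `p_used`, `outliers_cochran`, `outliers_grubbs`,
#'   `outliers_double_grubbs`, `mean`, `s_R`, `s_r`, `rsd_R`, `rsd_r`,
#'   `R_limit`, `r_limit`.
#' @export
#' @examples
#' tbl <- honey_saccharide_precision()
#' subset(tbl, analyte == "fructose" & sample == "A")
honey_saccharide_precision <- function() {
  samples <- LETTERS[1:6]
  block <- function(analyte, p, p_used, cochran, grubbs, dgrubbs,
                    mean, s_R, s_r, rsd_R, rsd_r, R_limit, r_limit)
    data.frame(analyte = analyte, sample = samples, p = p, p_used = p_used,
               outliers_cochran = cochran, outliers_grubbs = grubbs,
               outliers_double_grubbs = dgrubbs, mean = mean, s_R = s_R,
               s_r = s_r, rsd_R = rsd_R, rsd_r = rsd_r, R_limit = R_limit,
               r_limit = r_limit, stringsAsFactors = FALSE)
  rbind(
    block("fructose", 14, c(14, 13, 13, 14, 14, 14),
          c(0, 1, 1, 0, 0, 0), 0, 0,
          c(-24.33, -25.07, -24.40, -24.26, -24.49, -26.41),
          c(0.38, 0.28, 0.19, 0.27, 0.38, 0.37),
          c(0.13, 0.09, 0.09, 0.08, 0.08, 0.12),
          c(1.6, 1.1, 0.8, 1.1, 1.5, 1.4),
          c(0.5, 0.3, 0.4, 0.3, 0.3, 0.5),
          c(1.08, 0.79, 0.53, 0.75, 1.05, 1.04),
          c(0.36, 0.24, 0.24, 0.23, 0.21, 0.33)),
    block("glucose", 14, c(13, 14, 12, 13, 14, 14),
          c(0, 0, 1, 0, 0, 0), c(1, 0, 1, 1, 0, 0), 0,
          c(-24.43, -24.47, -23.58, -23.71, -24.53, -26.03),
          c(0.31, 0.43, 0.34, 0.33, 0.29, 0.42),
          c(0.10, 0.10, 0.12, 0.13, 0.12, 0.12),
          c(1.3, 1.8, 1.5, 1.4, 1.2, 1.6),
          c(0.4, 0.4, 0.5, 0.5, 0.5, 0.5),
          c(0.85, 1.20, 0.96, 0.92, 0.81, 1.18),
          c(0.27, 0.29, 0.33, 0.36, 0.32, 0.33)),
    block("disaccharides", 13, c(13, 13, 13, 11, 13, 13),
          0, 0, c(0, 0, 0, 2, 0, 0),
          c(-24.85, -26.27, -25.23, -25.13, -24.88, -27.01),
          c(0.35, 0.34, 0.36, 0.24, 0.36, 0.31),
          c(0.18, 0.08, 0.24, 0.15, 0.14, 0.12),
          c(1.4, 1.3, 1.4, 1.0, 1.45, 1.1),
          c(0.7, 0.3, 1.0, 0.6, 0.6, 0.4),
          c(0.99, 0.96, 1.01, 0.67, 1.01, 0.86),
          c(0.49, 0.23, 0.68, 0.41, 0.39, 0.34)),
    block("trisaccharides", c(10, 13, 13, 13, 10, 10),
          c(10, 12, 13, 13, 9, 10),
          c(0, 0, 0, 0, 1, 0), c(0, 1, 0, 0, 0, 0), 0,
          c(-24.05, -26.74, -24.69, -25.18, -22.73, -25.73),
          c(0.68, 0.36, 0.35, 0.50, 0.45, 0.57),
          c(0.68, 0.19, 0.23, 0.25, 0.15, 0.38),
          c(2.8, 1.4, 1.4, 2.0, 2.0, 2.2),
          c(2.8, 0.7, 0.9, 1.0, 0.7, 1.5),
          c(1.90, 1.02, 0.98, 1.40, 1.26, 1.59),
          c(1.90, 0.52, 0.64, 0.70, 0.42, 1.07)))
}

#' Recompute derived precision quantities from tabulated means and SDs
#'
#' From the `mean`, `s_r` and `s_R` columns of a precision summary,
#' recomputes the relative SDs (100 s / |mean|, percent) and the 2.80-factor
#' limits at full precision.  Because published tables print s to 2 decimals
#' but derive limits and relative SDs from the unrounded s, recomputed
#' values can differ from printed ones by up to the propagated printing
#' uncertainty (2.80 x 0.005 for the limits).
#'
#' @param tbl data.frame with columns `mean`, `s_r`, `s_R` (e.g.
#'   [honey_saccharide_precision()]).
#' @return `tbl` with added full-precision columns `rsd_r_calc`,
#'   `rsd_R_calc`, `r_limit_calc`, `R_limit_calc`.
#' @export
recompute_derived <- function(tbl) {
  stopifnot(all(c("mean", "s_r", "s_R") %in% names(tbl)))
  tbl$rsd_r_calc <- 100 * tbl$s_r / abs(tbl$mean)
  tbl$rsd_R_calc <- 100 * tbl$s_R / abs(tbl$mean)
  tbl$r_limit_calc <- 2.80 * tbl$s_r
  tbl$R_limit_calc <- 2.80 * tbl$s_R
  tbl
}

#' Range of recomputed relative SDs over a set of analytes
#'
#' Recomputes relative SDs from tabulated means and SDs, takes the min and
#' max over the selected analytes' cells and rounds half-up to report
#' precision (1 decimal).  This reproduces headline range summaries of the
#' form "reproducibility RSD between 0.8 and 1.8% across the
#' monosaccharide cells".
#'
#' @param tbl a precision summary table (default the built-in published one).
#' @param analytes analyte labels to pool.
#' @param quantity `"rsd_R"` or `"rsd_r"`.
#' @param digits rounding at report precision (default 1 decimal).
#' @return named numeric `c(min = ..., max = ...)`.
#' @export
#' @examples
#' rsd_bounds(analytes = c("fructose", "glucose"), quantity = "rsd_R")
rsd_bounds <- function(tbl = honey_saccharide_precision(),
                       analytes, quantity = c("rsd_R", "rsd_r"),
                       digits = 1) {
  quantity <- match.arg(quantity)
  sub <- recompute_derived(tbl[tbl$analyte %in% analytes, , drop = FALSE])
  if (!nrow(sub))
    stop("lookup error: no rows for analytes ",
         paste(analytes, collapse = ", "), call. = FALSE)
  v <- sub[[paste0(quantity, "_calc")]]
  c(min = round_half_up(min(v), digits), max = round_half_up(max(v), digits))
}
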