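# Critical values for the outlier tests.
#
# Cochran: the statistic C = max(s_i^2) / sum(s_i^2) for p within-laboratory
# variances, each on nu = n - 1 degrees of freedom.  For one fixed i,
# s_i^2 / sum_j s_j^2 > c  iff  F_{nu,(p-1)nu} > (p-1) c / (1 - c), so with a
# union bound over the p laboratories the upper critical value is
#   c = Q / (Q + p - 1),  Q = qf(1 - alpha/p, nu, (p-1) nu).
# The bound is exact for c >= 1/2 (two shares cannot both exceed 1/2) and is
# within ~1e-3 of the Monte-Carlo quantile for the study design (p = 14,
# n = 2) elsewhere.  A seeded Monte-Carlo quantile is available as an
# alternative method and for unsupported regions.
#
# Single Grubbs (two-sided): classical closed form via Student t,
#   G = (p-1)/sqrt(p) * sqrt(t^2 / (p - 2 + t^2)),  t = qt(1 - alpha/(2p), p-2).
#
# Double Grubbs: the reduced-sum-of-squares ratio has no convenient closed
# form; critical values are tabulated by seeded Monte Carlo and cached for
# the session.  The internal tabulation seed depends only on (p, alpha, n_mc),
# never on user seeds, so critical values are reproducible constants.

mc_cache_get <- function(key, compute) {
  if (!is.null(.ilcprec_cache[[key]])) return(.ilcprec_cache[[key]])
  val <- compute()
  assign(key, val, envir = .ilcprec_cache)
  val
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Critical value of the Cochran variance-outlier statistic
#'
#' Upper critical value of C = max within-laboratory variance / sum of
#' within-laboratory variances, for `p` laboratories each measuring `n`
#' replicates of a normal quantity.  `method = "closed"` uses the
#' F-distribution union bound (exact when the value is at least 1/2);
#' `method = "mc"` draws a seeded Monte-Carlo null sample of the statistic
#' and returns its empirical quantile (cached per session).
#'
#' @param p number of laboratories (>= 3; the test is degenerate at p = 2,
#'   where C compares only two variances and the statistic cannot separate
#'   an outlying lab from its complement).
#' @param n replicates per laboratory (>= 2).
#' @param alpha upper-tail significance level in (0, 1).
#' @param method `"closed"` (default) or `"mc"`.
#' @param n_mc Monte-Carlo draws for `method = "mc"`.
#' @return critical value in (1/p, 1].
#' @export
#' @examples
#' cochran_critical(14, 2, 0.05)
cochran_critical <- function(p, n, alpha,
                             method = c("closed", "mc"), n_mc = 5e5) {
  method <- match.arg(method)
  if (!is_count(p) || p < 3)
    stop("domain error: Cochran critical value needs p >= 3 laboratories",
         call. = FALSE)
  if (!is_count(n) || n < 2)
    stop("domain error: Cochran test needs n >= 2 replicates per lab",
         call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("domain error: alpha must be in (0, 1)", call. = FALSE)
  nu <- n - 1
  if (method == "closed") {
    q <- qf(1 - alpha / p, nu, (p - 1) * nu)
    return(q / (q + p - 1))
  }
  key <- sprintf("cochran|%d|%d|%g|%g", p, n, alpha, n_mc)
  mc_cache_get(key, function() {
    with_seed(substream_seed(20210922L, "cochran-null", p, n, n_mc), {
      m <- matrix(rchisq(p * n_mc, nu) / nu, ncol = p)
      cmax <- Reduce(pmax, asplit(m, 2))
      unname(quantile(cmax / rowSums(m), 1 - alpha, names = FALSE))
    })
  })
}

#' Critical value of the single Grubbs statistic (two-sided)
#'
#' @param p number of laboratory means (>= 3).
#' @param alpha two-sided significance level in (0, 1).
#' @return critical value of G = max |x_i - mean| / sd.
#' @export
grubbs_single_critical <- function(p, alpha) {
  if (!is_count(p) || p < 3)
    stop("domain error: single Grubbs test needs p >= 3", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("domain error: alpha must be in (0, 1)", call. = FALSE)
  t <- qt(1 - alpha / (2 * p), p - 2)
  (p - 1) / sqrt(p) * sqrt(t^2 / (p - 2 + t^2))
}

# Monte-Carlo null sample of the double-Grubbs reduced-sum-of-squares ratio
# D = min(SS without two lowest, SS without two highest) / SS full,
# for p standard-normal "laboratory means".  Returns the sorted null draws.
double_grubbs_null <- function(p, n_mc = 5e5) {
  key <- sprintf("dgrubbs-null|%d|%g", p, n_mc)
  mc_cache_get(key, function() {
    with_seed(substream_seed(20210922L, "double-grubbs-null", p, n_mc), {
      m <- matrix(rnorm(p * n_mc), nrow = p)
      # column-wise sort in one pass: order by column index then value
      s <- matrix(m[order(col(m), m)], nrow = p)
      tot <- colSums(s); tot2 <- colSums(s^2)
      ss_full <- tot2 - tot^2 / p
      ss_hi <- (tot2 - s[p, ]^2 - s[p - 1, ]^2) -
        (tot - s[p, ] - s[p - 1, ])^2 / (p - 2)
      ss_lo <- (tot2 - s[1, ]^2 - s[2, ]^2) -
        (tot - s[1, ] - s[2, ])^2 / (p - 2)
      sort(pmin(ss_hi, ss_lo) / ss_full)
    })
  })
}

#' Critical value of the double Grubbs statistic
#'
#' Lower critical value of the reduced-sum-of-squares ratio: the sum of
#' squares about the mean after removing the pair of lowest (or highest)
#' values, divided by the full sum of squares; the more extreme (smaller)
#' of the two sides is tested.  A small ratio indicates an outlying pair.
#' Tabulated by seeded Monte Carlo and cached.
#'
#' @param p number of laboratory means (>= 5).
#' @param alpha significance level in (0, 1); rejection when the observed
#'   ratio falls below the returned value.
#' @param n_mc Monte-Carlo draws for the tabulation.
#' @return lower critical value in (0, 1).
#' @export
grubbs_double_critical <- function(p, alpha, n_mc = 5e5) {
  if (!is_count(p) || p < 5)
    stop("domain error: double Grubbs test needs p >= 5", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("domain error: alpha must be in (0, 1)", call. = FALSE)
  unname(quantile(double_grubbs_null(p, n_mc), alpha, names = FALSE))
}
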