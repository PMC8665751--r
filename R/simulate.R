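#' Specify a synthetic ILC simulation
#'
#' The generator draws y_ijk = mu(analyte, sample) + B_i + e_ijk with
#' laboratory biases B_i ~ N(0, s_L^2) and replicate errors
#' e_ijk ~ N(0, s_r^2) — the classical random-effects model behind the
#' repeatability/reproducibility decomposition.  By default one bias per
#' (laboratory, analyte) is shared across samples (laboratories are
#' systematically biased); `shared_bias = FALSE` draws an independent bias
#' per cell.  Outliers are injected explicitly so ground truth stays known:
#' a `bias_shift` adds a fixed offset to one laboratory's bias in selected
#' cells, a `variance_inflation` multiplies its replicate-error SD.
#'
#' @param p number of laboratories (>= 2).
#' @param n replicates per laboratory (>= 1).
#' @param samples character vector of sample identifiers.
#' @param mu true means in per mil: a single number, a named vector (one
#'   entry per analyte), or an analyte x sample matrix with dimnames.
#' @param analytes analyte labels; defaults to the names of `mu` when given.
#' @param s_r replicate (repeatability) SD in per mil; scalar or named
#'   per-analyte vector.
#' @param s_L laboratory-bias SD in per mil; scalar or named per-analyte
#'   vector.
#' @param outliers data.frame of injections with columns `lab`, `sample`,
#'   `analyte`, `kind` (`"bias_shift"` or `"variance_inflation"`),
#'   `magnitude`; `NA` in `sample`/`analyte` selects all.
#' @param seed master integer seed; fully determines the output.
#' @param shared_bias share each laboratory's bias across samples (default
#'   TRUE).
#' @return object of class `ilc_sim_spec`.
#' @export
ilc_sim_spec <- function(p = 14, n = 2, samples = LETTERS[1:6],
                         mu = -25, analytes = NULL,
                         s_r = 0.10, s_L = 0.27,
                         outliers = NULL, seed = 1L, shared_bias = TRUE) {
  if (!is_count(p) || p < 2) stop("p must be an integer >= 2", call. = FALSE)
  if (!is_count(n)) stop("n must be a positive integer", call. = FALSE)
  if (is.matrix(mu)) {
    if (is.null(rownames(mu)) || is.null(colnames(mu)))
      stop("a mu matrix needs analyte rownames and sample colnames",
           call. = FALSE)
    analytes <- rownames(mu)
    samples <- colnames(mu)
  } else if (is.null(analytes)) {
    analytes <- names(mu) %||% "analyte"
  }
  mu_of <- expand_mu(mu, analytes, samples)
  s_r <- expand_per_analyte(s_r, analytes, "s_r")
  s_L <- expand_per_analyte(s_L, analytes, "s_L")
  if (any(s_r < 0) || any(s_L < 0))
    stop("validation error: s_r and s_L must be non-negative", call. = FALSE)
  outliers <- validate_injections(outliers, p, samples, analytes)
  structure(list(p = as.integer(p), n = as.integer(n), samples = samples,
                 analytes = analytes, mu = mu_of, s_r = s_r, s_L = s_L,
                 outliers = outliers, seed = as.integer(seed),
                 shared_bias = isTRUE(shared_bias)),
            class = "ilc_sim_spec")
}

expand_mu <- function(mu, analytes, samples) {
  m <- matrix(NA_real_, length(analytes), length(samples),
              dimnames = list(analytes, samples))
  if (is.matrix(mu)) {
    m[] <- mu[analytes, samples]
  } else if (length(mu) == 1 && is.null(names(mu))) {
    m[] <- mu
  } else {
    if (!all(analytes %in% names(mu)))
      stop("mu must name every analyte", call. = FALSE)
    for (a in analytes) m[a, ] <- mu[[a]]
  }
  if (anyNA(m)) stop("mu contains missing values", call. = FALSE)
  m
}

expand_per_analyte <- function(x, analytes, what) {
  if (length(x) == 1 && is.null(names(x)))
    return(setNames(rep(as.numeric(x), length(analytes)), analytes))
  if (!all(analytes %in% names(x)))
    stop("validation error: ", what, " must name every analyte", call. = FALSE)
  setNames(as.numeric(x[analytes]), analytes)
}

validate_injections <- function(outliers, p, samples, analytes) {
  if (is.null(outliers) || (is.data.frame(outliers) && nrow(outliers) == 0))
    return(data.frame(lab = character(), sample = character(),
                      analyte = character(), kind = character(),
                      magnitude = numeric(), stringsAsFactors = FALSE))
  needed <- c("lab", "sample", "analyte", "kind", "magnitude")
  if (!is.data.frame(outliers) || !all(needed %in% names(outliers)))
    stop("configuration error: outliers needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  labs <- sim_lab_ids(p)
  bad <- setdiff(outliers$lab, labs)
  if (length(bad))
    stop("configuration error: unknown lab in outlier selector: ", bad[1],
         call. = FALSE)
  bad <- setdiff(stats::na.omit(outliers$sample), samples)
  if (length(bad))
    stop("configuration error: unknown sample in outlier selector: ", bad[1],
         call. = FALSE)
  bad <- setdiff(stats::na.omit(outliers$analyte), analytes)
  if (length(bad))
    stop("configuration error: unknown analyte in outlier selector: ", bad[1],
         call. = FALSE)
  bad <- setdiff(outliers$kind, c("bias_shift", "variance_inflation"))
  if (length(bad))
    stop("configuration error: unknown outlier kind: ", bad[1], call. = FALSE)
  outliers[needed]
}

sim_lab_ids <- function(p) sprintf("L%02d", seq_len(p))

#' Simulate a synthetic ILC dataset
#'
#' Deterministic under the spec's master seed: every random draw comes from a
#' substream seeded by a stable hash of its coordinates (lab, analyte and,
#' for replicate errors, sample), so regenerating with the same seed is
#' byte-identical and adding an analyte or sample never perturbs the values
#' of existing cells.
#'
#' @param spec an [ilc_sim_spec()].
#' @return list with elements `dataset` (an [ilc_dataset()]) and `manifest`
#'   (the spec plus the realized per-laboratory biases and the injected
#'   outlier ground truth).
#' @export
#' @examples
#' sim <- simulate_ilc(ilc_sim_spec(p = 4, samples = "A", seed = 7))
#' sim$dataset
simulate_ilc <- function(spec) {
  stopifnot(inherits(spec, "ilc_sim_spec"))
  labs <- sim_lab_ids(spec$p)
  inj <- spec$outliers

  draw1 <- function(...) {
    with_seed(substream_seed(spec$seed, ...), rnorm(1))
  }

  n_cells <- length(spec$analytes) * spec$p * length(spec$samples)
  n_rows <- n_cells * spec$n
  col_lab <- character(n_rows); col_sample <- character(n_rows)
  col_analyte <- character(n_rows); col_rep <- integer(n_rows)
  col_y <- numeric(n_rows)
  b_lab <- character(n_cells); b_analyte <- character(n_cells)
  b_sample <- character(n_cells); b_bias <- numeric(n_cells)
  i_row <- 0L; i_bias <- 0L
  for (a in spec$analytes) {
    for (lab in labs) {
      if (spec$shared_bias) {
        b <- spec$s_L[[a]] * draw1("bias", lab, a)
        i_bias <- i_bias + 1L
        b_lab[i_bias] <- lab; b_analyte[i_bias] <- a
        b_sample[i_bias] <- NA_character_; b_bias[i_bias] <- b
      }
      for (s in spec$samples) {
        if (!spec$shared_bias) {
          b <- spec$s_L[[a]] * draw1("bias", lab, a, s)
          i_bias <- i_bias + 1L
          b_lab[i_bias] <- lab; b_analyte[i_bias] <- a
          b_sample[i_bias] <- s; b_bias[i_bias] <- b
        }
        sel <- inj$lab == lab &
          (is.na(inj$sample) | inj$sample == s) &
          (is.na(inj$analyte) | inj$analyte == a)
        shift <- sum(inj$magnitude[sel & inj$kind == "bias_shift"])
        infl <- prod(inj$magnitude[sel & inj$kind == "variance_inflation"])
        e <- with_seed(substream_seed(spec$seed, "error", lab, a, s),
                       rnorm(spec$n))
        idx <- i_row + seq_len(spec$n)
        col_lab[idx] <- lab; col_sample[idx] <- s; col_analyte[idx] <- a
        col_rep[idx] <- seq_len(spec$n)
        col_y[idx] <- spec$mu[a, s] + b + shift + spec$s_r[[a]] * infl * e
        i_row <- i_row + spec$n
      }
    }
  }
  measurements <- data.frame(lab = col_lab, sample = col_sample,
                             analyte = col_analyte, replicate = col_rep,
                             delta13c = col_y, stringsAsFactors = FALSE)
  bias_tab <- data.frame(lab = b_lab[seq_len(i_bias)],
                         analyte = b_analyte[seq_len(i_bias)],
                         sample = b_sample[seq_len(i_bias)],
                         bias = b_bias[seq_len(i_bias)],
                         stringsAsFactors = FALSE)
  ds <- ilc_dataset(measurements, design_n = spec$n,
                    metadata = list(source = "synthetic", seed = spec$seed))
  manifest <- structure(list(spec = spec,
                             biases = bias_tab,
                             outliers = inj),
                        class = "ilc_sim_manifest")
  list(dataset = ds, manifest = manifest)
}

#' Study-design simulation preset
#'
#' An [ilc_sim_spec()] emulating the honey-saccharide ILC design: 14
#' laboratories, 6 samples (A-F), 5 analyte classes, duplicate measurements.
#' True means for fructose, glucose, disaccharides and trisaccharides come
#' from the built-in published summary ([honey_saccharide_precision()]);
#' per-analyte s_r is the published median and s_L the median of
#' sqrt(s_R^2 - s_r^2).  The oligosaccharide fraction has no published
#' precision table, so it uses a documented choice of mu = -25 per mil,
#' s_r = 0.25, s_L = 0.45 (slightly noisier than trisaccharides, as the
#' hardest fraction to integrate).
#'
#' @param seed master seed.
#' @param outliers optional injection data.frame (see [ilc_sim_spec()]).
#' @return an `ilc_sim_spec`.
#' @export
honey_ilc_spec <- function(seed = 1L, outliers = NULL) {
  tbl <- honey_saccharide_precision()
  analytes <- c(unique(tbl$analyte), "oligosaccharides")
  samples <- sort(unique(tbl$sample))
  mu <- matrix(NA_real_, length(analytes), length(samples),
               dimnames = list(analytes, samples))
  s_r <- s_L <- setNames(numeric(length(analytes)), analytes)
  for (a in unique(tbl$analyte)) {
    sub <- tbl[tbl$analyte == a, ]
    mu[a, sub$sample] <- sub$mean
    s_r[[a]] <- median(sub$s_r)
    s_L[[a]] <- median(sqrt(pmax(sub$s_R^2 - sub$s_r^2, 0)))
  }
  mu["oligosaccharides", ] <- -25
  s_r[["oligosaccharides"]] <- 0.25
  s_L[["oligosaccharides"]] <- 0.45
  ilc_sim_spec(p = 14, n = 2, samples = samples, mu = mu,
               s_r = s_r, s_L = s_L, outliers = outliers, seed = seed)
}

#' Empirical null rejection rate of an outlier test
#'
#' Simulates `n_reps` independent cells under the spec's null model (no
#' injected outliers) and returns the fraction in which the named test
#' rejects at `alpha`.  Used to validate the critical-value machinery: the
#' rate must sit inside the binomial envelope around `alpha`.
#'
#' @param spec an [ilc_sim_spec()] without injections (its `p`, `n`, first
#'   analyte's `s_r`/`s_L` and `seed` are used).
#' @param test `"cochran"`, `"grubbs_single"` or `"grubbs_double"`.
#' @param alpha rejection level in \[0, 1); `alpha = 0` never rejects.
#' @param n_reps number of simulated cells.
#' @return empirical rejection rate in \[0, 1\].
#' @export
null_rejection_rate <- function(spec, test, alpha, n_reps = 10000) {
  stopifnot(inherits(spec, "ilc_sim_spec"))
  if (nrow(spec$outliers))
    stop("configuration error: null_rejection_rate needs a spec without injected outliers",
         call. = FALSE)
  test <- match.arg(test, c("cochran", "grubbs_single", "grubbs_double"))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must be in [0, 1)", call. = FALSE)
  if (alpha == 0) return(0)
  p <- spec$p; n <- spec$n
  a1 <- spec$analytes[1]
  with_seed(substream_seed(spec$seed, "null-rate", test, alpha, n_reps), {
    if (test == "cochran") {
      crit <- cochran_critical(p, n, alpha, method = "mc")
      v <- matrix(rchisq(p * n_reps, n - 1) / (n - 1), ncol = p)
      mean(Reduce(pmax, asplit(v, 2)) / rowSums(v) > crit)
    } else {
      # laboratory means under the null: iid normal with variance
      # s_L^2 + s_r^2 / n (both tests are location-scale invariant)
      sd_mean <- sqrt(spec$s_L[[a1]]^2 + spec$s_r[[a1]]^2 / n)
      m <- matrix(rnorm(p * n_reps, sd = sd_mean), nrow = p)
      if (test == "grubbs_single") {
        crit <- grubbs_single_critical(p, alpha)
        cm <- colMeans(m)
        cs <- sqrt((colSums(m^2) - p * cm^2) / (p - 1))
        gmax <- Reduce(pmax, asplit(abs(m - rep(cm, each = p)), 1))
        mean(gmax / cs > crit)
      } else {
        crit <- grubbs_double_critical(p, alpha)
        s <- matrix(m[order(col(m), m)], nrow = p)
        tot <- colSums(s); tot2 <- colSums(s^2)
        ss_full <- tot2 - tot^2 / p
        ss_hi <- (tot2 - s[p, ]^2 - s[p - 1, ]^2) -
          (tot - s[p, ] - s[p - 1, ])^2 / (p - 2)
        ss_lo <- (tot2 - s[1, ]^2 - s[2, ]^2) -
          (tot - s[1, ] - s[2, ])^2 / (p - 2)
        mean(pmin(ss_hi, ss_lo) / ss_full < crit)
      }
    }
  })
}

#' Write a simulation manifest as JSON
#'
#' @param manifest the `ilc_sim_manifest` from [simulate_ilc()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ilc_sim_manifest"))
  spec <- manifest$spec
  jsonlite::write_json(
    list(spec = list(p = spec$p, n = spec$n, samples = spec$samples,
                     analytes = spec$analytes, mu = spec$mu,
                     s_r = as.list(spec$s_r), s_L = as.list(spec$s_L),
                     seed = spec$seed, shared_bias = spec$shared_bias),
         biases = manifest$biases,
         outliers = manifest$outliers),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
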