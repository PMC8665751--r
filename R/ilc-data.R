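#' Construct an ILC measurement dataset
#'
#' An interlaboratory-comparison (ILC) dataset holds one row per
#' (laboratory, sample, analyte, replicate) with a delta-13C value in
#' per mil vs VPDB.  The constructor validates the key structure; soft
#' plausibility checks are collected by [validate_ilc()].
#'
#' @param measurements data.frame with columns `lab`, `sample`, `analyte`,
#'   `replicate`, `delta13c`.
#' @param design_n declared replicate count per laboratory (the study design
#'   used duplicates, `design_n = 2`).
#' @param metadata free-form named list of study descriptors.
#' @return object of class `ilc_dataset`.
#' @export
#' @examples
#' m <- data.frame(lab = "L1", sample = "A", analyte = "fructose",
#'                 replicate = 1:2, delta13c = c(-24.1, -24.3))
#' ilc_dataset(m)
ilc_dataset <- function(measurements, design_n = 2L, metadata = list()) {
  required <- c("lab", "sample", "analyte", "replicate", "delta13c")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(measurements) == 0)
    stop("empty-input error: dataset has no measurements", call. = FALSE)
  if (!is_count(design_n))
    stop("design_n must be a positive integer", call. = FALSE)

  m <- measurements[required]
  m$lab <- as.character(m$lab)
  m$sample <- as.character(m$sample)
  m$analyte <- as.character(m$analyte)
  m$replicate <- as.integer(m$replicate)
  m$delta13c <- as.numeric(m$delta13c)

  if (anyNA(m$replicate) || any(m$replicate < 1))
    stop("replicate indices must be positive integers", call. = FALSE)
  if (any(!is.finite(m$delta13c)))
    stop("delta13c values must be finite numbers (row ",
         paste(which(!is.finite(m$delta13c)), collapse = ", "), ")",
         call. = FALSE)

  key <- paste(m$lab, m$sample, m$analyte, m$replicate, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("integrity error: duplicate (lab, sample, analyte, replicate) key: ",
         gsub("\\|", ", ", dup), call. = FALSE)
  }
  # replicate indices per (lab, sample, analyte) must be 1..k with no gaps
  grp <- split(m$replicate, paste(m$lab, m$sample, m$analyte, sep = "|"))
  bad <- names(grp)[!vapply(grp, function(r) all(sort(r) == seq_along(r)), TRUE)]
  if (length(bad))
    stop("integrity error: replicate indices not 1..k for (",
         gsub("\\|", ", ", bad[1]), ")", call. = FALSE)

  structure(list(measurements = m,
                 design_n = as.integer(design_n),
                 metadata = metadata),
            class = "ilc_dataset")
}

#' @export
print.ilc_dataset <- function(x, ...) {
  m <- x$measurements
  cat("ILC dataset: ", nrow(m), " measurements\n",
      "  labs: ", length(unique(m$lab)),
      "  samples: ", length(unique(m$sample)),
      "  analytes: ", length(unique(m$analyte)),
      "  design replicates: ", x$design_n, "\n", sep = "")
  invisible(x)
}

#' Read an ILC dataset from a long-format CSV file
#'
#' Expects a header with columns `lab`, `sample`, `analyte`, `replicate`,
#' `delta13c` (any order, case-insensitive).  Decimal separator is the dot;
#' values using a decimal comma are rejected with an explicit message rather
#' than silently misparsed.
#'
#' @param path CSV file path (RFC 4180, UTF-8).
#' @param design_n declared replicates per laboratory.
#' @return an [ilc_dataset()].
#' @export
read_ilc_long <- function(path, design_n = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (nrow(raw) == 0) stop("empty-input error: no data rows in ", path, call. = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  required <- c("lab", "sample", "analyte", "replicate", "delta13c")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  if (any(grepl(",", raw$delta13c, fixed = TRUE)))
    stop("decimal commas detected in delta13c (rows ",
         paste(utils::head(which(grepl(",", raw$delta13c, fixed = TRUE)), 5),
               collapse = ", "),
         "); use dot as decimal separator", call. = FALSE)
  val <- suppressWarnings(as.numeric(raw$delta13c))
  if (anyNA(val))
    stop("numeric parse failure in delta13c at data row(s): ",
         paste(which(is.na(val)), collapse = ", "), call. = FALSE)
  rep_i <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(rep_i))
    stop("numeric parse failure in replicate at data row(s): ",
         paste(which(is.na(rep_i)), collapse = ", "), call. = FALSE)

  ilc_dataset(data.frame(lab = raw$lab, sample = raw$sample,
                         analyte = raw$analyte, replicate = rep_i,
                         delta13c = val, stringsAsFactors = FALSE),
              design_n = design_n)
}

#' Write an ILC dataset as long-format CSV
#'
#' @param ds an [ilc_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ilc_long <- function(ds, path) {
  stopifnot(inherits(ds, "ilc_dataset"))
  write.csv(ds$measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ILC dataset from a wide reporting template
#'
#' Convenience importer for the common reporting-template layout: one row per
#' (lab, sample), one column pair per analyte named `<analyte>_1`,
#' `<analyte>_2`, ... for the replicates.  Mapped onto the long model; empty
#' cells are dropped (a laboratory that reported only one replicate is
#' retained with that single value).
#'
#' @inheritParams read_ilc_long
#' @export
read_ilc_wide <- function(path, design_n = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  if (!all(c("lab", "sample") %in% names(raw)))
    stop("schema error: wide template needs 'lab' and 'sample' columns",
         call. = FALSE)
  value_cols <- grep("^.+_[0-9]+$", names(raw), value = TRUE)
  if (!length(value_cols))
    stop("schema error: no '<analyte>_<replicate>' value columns found",
         call. = FALSE)
  pieces <- lapply(value_cols, function(cn) {
    analyte <- sub("_[0-9]+$", "", cn)
    rep_i <- as.integer(sub("^.+_", "", cn))
    v <- raw[[cn]]
    keep <- !is.na(v) & nzchar(v)
    if (any(grepl(",", v[keep], fixed = TRUE)))
      stop("decimal commas detected in column ", cn, call. = FALSE)
    data.frame(lab = raw$lab[keep], sample = raw$sample[keep],
               analyte = analyte, replicate = rep_i,
               delta13c = as.numeric(v[keep]), stringsAsFactors = FALSE)
  })
  ilc_dataset(do.call(rbind, pieces), design_n = design_n)
}

#' Validate an ILC dataset (collector pattern)
#'
#' Runs soft checks and returns all findings without mutating the dataset:
#' plausible-range warning for delta-13C outside \[-40, 0\] per mil (honey
#' sugars), design-imbalance warnings where a laboratory's replicate count
#' differs from `design_n`, and errors for cells with fewer than two
#' laboratories (no between-laboratory precision can be estimated there).
#'
#' @param ds an [ilc_dataset()].
#' @return data.frame with columns `severity` (`"warning"`/`"error"`),
#'   `key`, `message`; zero rows when the dataset is clean.
#' @export
validate_ilc <- function(ds) {
  stopifnot(inherits(ds, "ilc_dataset"))
  m <- ds$measurements
  issues <- list()
  add <- function(severity, key, message)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, key = key, message = message,
      stringsAsFactors = FALSE)

  out_of_range <- which(m$delta13c < -40 | m$delta13c > 0)
  for (i in out_of_range)
    add("warning", paste(m$lab[i], m$sample[i], m$analyte[i], m$replicate[i],
                         sep = ", "),
        sprintf("delta13c = %.2f permil outside plausible honey-sugar range [-40, 0]",
                m$delta13c[i]))

  grp <- split(seq_len(nrow(m)), paste(m$lab, m$sample, m$analyte, sep = "|"))
  for (g in names(grp)) {
    k <- length(grp[[g]])
    if (k != ds$design_n)
      add("warning", gsub("\\|", ", ", g),
          sprintf("%d replicate(s) reported where design specifies %d",
                  k, ds$design_n))
  }

  cells <- unique(m[c("analyte", "sample")])
  for (i in seq_len(nrow(cells))) {
    sel <- m$analyte == cells$analyte[i] & m$sample == cells$sample[i]
    p <- length(unique(m$lab[sel]))
    if (p < 2)
      add("error", paste(cells$analyte[i], cells$sample[i], sep = ", "),
          sprintf("only %d laboratory in cell; precision statistics need at least 2", p))
  }

  if (!length(issues))
    return(data.frame(severity = character(), key = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Extract one analysis cell from an ILC dataset
#'
#' A cell is the per-(analyte, sample) slice of laboratory x replicate values
#' on which all screening and precision statistics operate.  Laboratories are
#' sorted lexicographically; replicate values keep their replicate order.
#' The cell is a pure projection: the source dataset is never modified.
#'
#' @param ds an [ilc_dataset()].
#' @param analyte analyte label.
#' @param sample sample identifier.
#' @return object of class `ilc_cell` with elements `analyte`, `sample`,
#'   `labs`, `values` (named list of numeric vectors), `p` (lab count) and
#'   `n_i` (per-lab replicate counts).
#' @export
extract_cell <- function(ds, analyte, sample) {
  stopifnot(inherits(ds, "ilc_dataset"))
  m <- ds$measurements
  sel <- m$analyte == analyte & m$sample == sample
  if (!any(sel))
    stop("lookup error: no measurements for analyte '", analyte,
         "', sample '", sample, "'", call. = FALSE)
  sub <- m[sel, , drop = FALSE]
  labs <- sort(unique(sub$lab))
  values <- lapply(labs, function(l) {
    r <- sub[sub$lab == l, , drop = FALSE]
    r$delta13c[order(r$replicate)]
  })
  names(values) <- labs
  new_cell(analyte, sample, values)
}

# internal cell constructor shared by extract_cell and screening
new_cell <- function(analyte, sample, values) {
  stopifnot(length(values) > 0, all(lengths(values) > 0))
  structure(list(analyte = analyte, sample = sample,
                 labs = names(values), values = values,
                 p = length(values),
                 n_i = unname(lengths(values))),
            class = "ilc_cell")
}

#' Build a cell directly from per-laboratory values
#'
#' Mostly useful in simulations and tests where no full dataset exists.
#'
#' @param values named list of numeric replicate vectors, one entry per lab
#'   (unnamed lists get labs `L01`, `L02`, ...).
#' @param analyte,sample labels stored on the cell.
#' @export
as_ilc_cell <- function(values, analyte = "analyte", sample = "S") {
  if (is.null(names(values)))
    names(values) <- sprintf("L%02d", seq_along(values))
  values <- values[order(names(values))]
  new_cell(analyte, sample, lapply(values, as.numeric))
}

#' @export
print.ilc_cell <- function(x, ...) {
  cat("ILC cell (", x$analyte, ", sample ", x$sample, "): p = ", x$p,
      " labs, replicates ", paste(range(x$n_i), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' List the non-empty cells of a dataset
#'
#' @param ds an [ilc_dataset()].
#' @return data.frame with columns `analyte`, `sample`, `p`, `n_total`.
#' @export
list_cells <- function(ds) {
  stopifnot(inherits(ds, "ilc_dataset"))
  m <- ds$measurements
  cells <- unique(m[c("analyte", "sample")])
  cells <- cells[order(cells$analyte, cells$sample), , drop = FALSE]
  cells$p <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- m$analyte == cells$analyte[i] & m$sample == cells$sample[i]
    length(unique(m$lab[sel]))
  }, integer(1))
  cells$n_total <- vapply(seq_len(nrow(cells)), function(i)
    sum(m$analyte == cells$analyte[i] & m$sample == cells$sample[i]),
    integer(1))
  rownames(cells) <- NULL
  cells
}
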