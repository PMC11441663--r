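#' Construct a causal dataset in the positional layout
#'
#' Validates a rectangular table whose first column is the observed outcome,
#' second column the binary treatment, followed by the block of error-prone
#' surrogate confounder columns and then the error-free confounder columns.
#' When a confounder has replicate surrogate measurements, its replicates
#' occupy consecutive columns and their counts are given by `rm`.
#'
#' @param data A data frame (or matrix) in the positional layout described
#'   above. All columns must be numeric and free of missing values.
#' @param px Number of error-prone confounders (columns 3 onward). `px = 0`
#'   declares every confounder error-free.
#' @param rm Integer vector of length `px` giving the replicate count for each
#'   error-prone confounder; `0` (or `1`) means a single surrogate column,
#'   values `>= 2` mean that many consecutive replicate columns. Default: no
#'   replicates.
#' @return A tibble of class `causal_data` carrying the layout as attributes
#'   (`px`, `pz`, `rm`, and the column index of every confounder block).
#' @examples
#' d <- data.frame(y = rnorm(4), t = c(0, 1, 0, 1), x1 = rnorm(4), z1 = rnorm(4))
#' cd <- causal_data(d, px = 1)
#' attr(cd, "pz")
#' @export
causal_data <- function(data, px = 0L, rm = NULL) {
  if (is.matrix(data)) data <- as.data.frame(data)
  if (!is.data.frame(data)) stop("`data` must be a data frame or matrix.", call. = FALSE)
  if (ncol(data) < 2L) stop("`data` needs at least outcome and treatment columns.", call. = FALSE)
  if (nrow(data) < 2L) stop("At least two rows are required.", call. = FALSE)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("All columns must be numeric.", call. = FALSE)
  }
  assert_no_missing(data, "the dataset")

  px <- as.integer(px)
  if (px < 0L) stop("`px` must be non-negative.", call. = FALSE)
  if (is.null(rm)) rm <- rep(0L, px)
  rm <- as.integer(rm)
  if (length(rm) != px) {
    stop(sprintf("`rm` must have length px = %d (got %d).", px, length(rm)), call. = FALSE)
  }
  if (any(rm < 0L)) stop("`rm` entries must be >= 0.", call. = FALSE)

  y <- data[[1L]]
  trt <- data[[2L]]
  assert_binary(trt)
  if (length(unique(trt)) < 2L) {
    stop("Both treatment groups must be non-empty.", call. = FALSE)
  }

  width <- pmax(rm, 1L)          # columns owned by each error-prone confounder
  n_x_cols <- sum(width)
  pz <- ncol(data) - 2L - n_x_cols
  if (pz < 0L) {
    stop(sprintf(
      "Layout failure: px = %d with rm = c(%s) needs %d confounder columns but only %d are present.",
      px, paste(rm, collapse = ","), n_x_cols, ncol(data) - 2L
    ), call. = FALSE)
  }

  # consecutive column blocks, one per error-prone confounder
  x_cols <- vector("list", px)
  at <- 3L
  for (j in seq_len(px)) {
    x_cols[[j]] <- seq.int(at, length.out = width[j])
    at <- at + width[j]
  }
  z_cols <- if (pz > 0L) seq.int(at, length.out = pz) else integer(0)

  out <- tibble::as_tibble(data)
  structure(out,
            class = c("causal_data", class(out)),
            px = px, pz = pz, rm = rm,
            x_cols = x_cols, z_cols = z_cols)
}

#' Read a causal dataset from delimited text
#'
#' @param path File path to a delimited text file with a header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @inheritParams causal_data
#' @return A `causal_data` tibble.
#' @export
read_causal_data <- function(path, px = 0L, rm = NULL, delim = ",") {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  causal_data(raw, px = px, rm = rm)
}

#' Write a causal dataset to delimited text
#'
#' Round-trips exactly with [read_causal_data()] given the same `px`/`rm`.
#'
#' @param ds A `causal_data` object.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_causal_data <- function(ds, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(ds), path, delim = delim)
  invisible(path)
}

# ---- accessors ------------------------------------------------------------

cd_outcome <- function(ds) ds[[1L]]
cd_treatment <- function(ds) ds[[2L]]
cd_px <- function(ds) attr(ds, "px")
cd_pz <- function(ds) attr(ds, "pz")
cd_rm <- function(ds) attr(ds, "rm")

# n x px matrix of working surrogates, one column per error-prone confounder.
# Replicated confounders are collapsed by `collapse` ("first" keeps the error
# covariance exactly Sigma_e for every row; "mean" averages replicates).
cd_xstar <- function(ds, collapse = c("first", "mean")) {
  collapse <- match.arg(collapse)
  px <- cd_px(ds)
  n <- nrow(ds)
  if (px == 0L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  cols <- attr(ds, "x_cols")
  out <- matrix(NA_real_, n, px)
  for (j in seq_len(px)) {
    block <- as.matrix(ds[, cols[[j]], drop = FALSE])
    out[, j] <- if (collapse == "first" || ncol(block) == 1L) block[, 1L] else rowMeans(block)
  }
  colnames(out) <- vapply(cols, function(ix) names(ds)[ix[1L]], character(1))
  out
}

cd_z <- function(ds) {
  zc <- attr(ds, "z_cols")
  m <- as.matrix(ds[, zc, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Per-subject replicate matrices (n_rep x px). Requires every rm entry >= 2;
# if replicate counts differ across confounders, the first min(rm) replicates
# of each are used so every subject yields one rectangular matrix.
cd_replicates <- function(ds) {
  px <- cd_px(ds)
  rm_ <- cd_rm(ds)
  if (px == 0L || all(rm_ <= 1L)) {
    stop("No replicate columns in this dataset (all rm <= 1).", call. = FALSE)
  }
  if (any(rm_ < 2L)) {
    stop("Replicate-based operations need every error-prone confounder replicated (rm >= 2); use the known-covariance or validation route otherwise.",
         call. = FALSE)
  }
  cols <- attr(ds, "x_cols")
  n_rep <- min(rm_)
  take <- lapply(seq_len(px), function(j) cols[[j]][seq_len(n_rep)])
  mat <- as.matrix(ds[, unlist(take), drop = FALSE])
  lapply(seq_len(nrow(ds)), function(i) {
    matrix(mat[i, ], nrow = n_rep, ncol = px)
  })
}

#' Build the treatment-model design matrix
#'
#' Prepends an intercept column of ones to the working confounder matrix:
#' one representative column per error-prone confounder (replicates collapsed
#' by `collapse`), followed by the error-free columns. Column count is always
#' `1 + px + pz` regardless of replication.
#'
#' @param ds A `causal_data` object.
#' @param collapse Replicate-collapse rule, `"first"` (default) or `"mean"`.
#' @return An `n x (1 + px + pz)` numeric matrix; first column identically 1.
#' @export
build_design <- function(ds, collapse = c("first", "mean")) {
  collapse <- match.arg(collapse)
  x <- cd_xstar(ds, collapse = collapse)
  z <- cd_z(ds)
  w <- cbind(`(Intercept)` = 1, x, z)
  rownames(w) <- NULL
  w
}

#' Positivity diagnostic for fitted propensity scores
#'
#' Counts propensities outside `[eps, 1 - eps]`. Diagnostic only; the input is
#' never modified.
#'
#' @param pi Numeric vector of fitted propensity scores.
#' @param eps Tolerance defining "practically 0 or 1" (default `1e-6`).
#' @return A tibble with `n`, `n_flagged`, and the offending indices
#'   (list-column `which`).
#' @export
check_positivity <- function(pi, eps = 1e-6) {
  if (length(pi) == 0L) stop("`pi` is empty.", call. = FALSE)
  bad <- which(pi < eps | pi > 1 - eps)
  tibble::tibble(n = length(pi), n_flagged = length(bad), which = list(bad))
}

#' Construct an external validation sample
#'
#' Pairs of true confounder values and their surrogates, measured on subjects
#' disjoint from the main sample, used to estimate the measurement-error
#' covariance by covariance additivity.
#'
#' @param x `m x px` table of true confounder values.
#' @param xstar `m x px` table of the paired surrogates.
#' @return A `validation_sample` object.
#' @export
validation_sample <- function(x, xstar) {
  x <- as.matrix(x); xstar <- as.matrix(xstar)
  storage.mode(x) <- "double"; storage.mode(xstar) <- "double"
  if (nrow(x) != nrow(xstar) || ncol(x) != ncol(xstar)) {
    stop("`x` and `xstar` must have identical dimensions.", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("A validation sample needs at least 2 rows.", call. = FALSE)
  assert_no_missing(x, "the validation sample")
  assert_no_missing(xstar, "the validation sample")
  structure(list(x = x, xstar = xstar, m = nrow(x)), class = "validation_sample")
}

#' Read a validation sample from delimited text
#'
#' The file holds the true-value block first (px columns), then the surrogate
#' block (px columns), with a header row.
#'
#' @param path File path.
#' @param px Number of error-prone confounders.
#' @param delim Field delimiter.
#' @return A `validation_sample` object.
#' @export
read_validation_sample <- function(path, px, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) != 2L * px) {
    stop(sprintf("Expected %d columns (true block then surrogate block), found %d.",
                 2L * px, ncol(raw)), call. = FALSE)
  }
  validation_sample(raw[, seq_len(px), drop = FALSE],
                    raw[, px + seq_len(px), drop = FALSE])
}
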