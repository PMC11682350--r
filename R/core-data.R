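#' @keywords internal
"_PACKAGE"

#' The fixed m/z axis
#'
#' All spectra in the package live on a fixed unit-resolution m/z grid from
#' 50 to 250 inclusive, i.e. 201 integer bins. Library matrices carry the
#' corresponding column names `mz_50` ... `mz_250`.
#'
#' @return Integer vector `50:250` (length 201).
#' @export
#' @examples
#' length(mz_axis())  # 201
mz_axis <- function() seq.int(50L, 250L)

#' @rdname mz_axis
#' @return `mz_labels()`: character vector `"mz_50"` ... `"mz_250"`.
#' @export
mz_labels <- function() paste0("mz_", mz_axis())

N_MZ <- 201L

#' Construct and validate a spectrum library
#'
#' A spectrum library is a plain numeric matrix: one row per oil, 201
#' columns of non-negative relative intensities on the grid of [mz_axis()].
#' Rownames are the oil names (unique, non-empty); columns are named
#' `mz_50` ... `mz_250`.
#'
#' @param x Numeric matrix, `n_oils x 201`, non-negative.
#' @param names Optional character vector of oil names; defaults to existing
#'   rownames.
#' @return The validated matrix with canonical dimnames.
#' @export
spectrum_library <- function(x, names = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(names)) names <- paste0("oil_", seq_len(nrow(x)))
  rownames(x) <- names
  colnames(x) <- mz_labels()[seq_len(ncol(x))]
  validate_spectrum_library(x)
  x
}

#' @rdname spectrum_library
#' @export
validate_spectrum_library <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("spectrum library must be a numeric matrix")
  if (ncol(x) != N_MZ)
    stop("spectrum library must have ", N_MZ, " intensity columns (m/z 50-250), got ",
         ncol(x))
  if (anyNA(x) ) stop("spectrum library contains missing values")
  if (any(x < 0)) stop("spectrum library contains negative intensities")
  nm <- rownames(x)
  if (is.null(nm) || any(!nzchar(nm))) stop("every oil needs a non-empty name")
  if (anyDuplicated(nm)) stop("duplicate oil names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  invisible(x)
}

#' Construct and validate a binary descriptor matrix
#'
#' One row per oil, one column per odor descriptor; entries are 0 (absent)
#' or 1 (present). Column names are the descriptor vocabulary, in order.
#'
#' @param x Numeric matrix of 0/1 entries.
#' @param names Optional oil names (rownames).
#' @param vocabulary Optional descriptor labels (colnames).
#' @return The validated matrix.
#' @export
descriptor_matrix <- function(x, names = rownames(x), vocabulary = colnames(x)) {
  x <- as.matrix(x)
  if (!is.null(names)) rownames(x) <- names
  if (!is.null(vocabulary)) colnames(x) <- vocabulary
  validate_descriptor_matrix(x)
  x
}

#' @rdname descriptor_matrix
#' @export
validate_descriptor_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("descriptor matrix must be a numeric matrix")
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop("descriptor matrix entries must be 0 or 1; found ", x[bad[1]],
         " at row ", i, " ('", rownames(x)[i], "'), column ", j,
         " ('", colnames(x)[j], "')")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("descriptor matrix needs unique column labels (the vocabulary)")
  empty <- colSums(x) == 0
  if (any(empty))
    warning("descriptor column(s) with no positive oil (untrainable class): ",
            paste(colnames(x)[empty], collapse = ", "))
  invisible(x)
}

#' Normalize a spectrum to unit maximum
#'
#' Scales a spectrum (or every row of a library) so its largest intensity is
#' exactly 1. This is the normalization applied before the descriptor
#' predictor sees a spectrum, and the map whose Jacobian the recipe search
#' uses. All-zero input is an error: it signals a degenerate recipe or an
#' empty library row rather than something to normalize silently.
#'
#' @param x Non-negative numeric vector (length 201) or matrix (rows are
#'   spectra).
#' @return Object of the same shape with row maxima equal to 1.
#' @export
#' @examples
#' s <- c(2, 4, 1, rep(0, 198))
#' max(max_normalize(s))  # 1
max_normalize <- function(x) {
  if (is.matrix(x)) {
    if (any(x < 0)) stop("negative intensities cannot be max-normalized")
    m <- apply(x, 1, max)
    if (any(m <= 0))
      stop("all-zero spectrum (row ", which(m <= 0)[1], ") cannot be max-normalized")
    return(x / m)
  }
  if (any(x < 0)) stop("negative intensities cannot be max-normalized")
  m <- max(x)
  if (m <= 0) stop("all-zero spectrum cannot be max-normalized")
  x / m
}

#' Normalize a recipe to unit sum
#'
#' Scales a non-negative vector of component mixing ratios so it sums to 1.
#' All-zero input is an error (a recipe with no components is meaningless
#' and the scaling would divide by zero).
#'
#' @param r Non-negative numeric vector of mixing ratios.
#' @return Vector proportional to `r` summing to 1.
#' @export
#' @examples
#' sum_normalize(rep(1, 20))  # uniform 0.05 start
sum_normalize <- function(r) {
  if (any(r < 0)) stop("negative mixing ratios cannot be sum-normalized")
  s <- sum(r)
  if (s <= 0) stop("all-zero recipe cannot be sum-normalized")
  r / s
}

#' Average replicate spectra with a relative noise floor
#'
#' Replicate measurements of one sample are averaged elementwise; bins of
#' the averaged spectrum below `noise_floor` times its maximum are then set
#' to zero. The floor is a simple documented pretreatment that removes
#' near-baseline chatter before library assembly.
#'
#' @param spectra Numeric matrix with one replicate per row (201 columns),
#'   or a list of numeric vectors of equal length.
#' @param noise_floor Fraction of the post-average maximum below which bins
#'   are zeroed. Default `1e-3` (0.1 percent).
#' @return Numeric vector: the averaged, floored spectrum.
#' @export
average_replicates <- function(spectra, noise_floor = 1e-3) {
  if (is.list(spectra)) {
    len <- vapply(spectra, length, integer(1))
    if (length(unique(len)) != 1)
      stop("replicates live on different m/z axes (lengths ",
           paste(unique(len), collapse = ", "), ")")
    spectra <- do.call(rbind, spectra)
  }
  if (!is.matrix(spectra)) spectra <- matrix(spectra, nrow = 1)
  if (any(spectra < 0)) stop("replicates contain negative intensities")
  avg <- colMeans(spectra)
  m <- max(avg)
  if (m > 0) avg[avg < noise_floor * m] <- 0
  avg
}

#' Binarize a real-valued descriptor vector
#'
#' Predictor outputs are real-valued (the output activation is a leaky
#' ReLU); labels are recovered by thresholding.
#'
#' @param x Numeric vector or matrix of predictions.
#' @param threshold Entries `>= threshold` become 1, the rest 0. Default 0.5.
#' @return 0/1 object of the same shape.
#' @export
binarize <- function(x, threshold = 0.5) {
  out <- (x >= threshold) * 1
  dimnames(out) <- dimnames(x)
  out
}
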