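#' Read and write spectrum libraries as CSV
#'
#' The canonical on-disk form is a comma-separated UTF-8 file with a `name`
#' column followed by 201 intensity columns headed `mz_50` ... `mz_250`
#' (`.` decimal point). `write_spectrum_library()` is the exact inverse of
#' `read_spectrum_library()` on valid libraries.
#'
#' @param path Path to the CSV file.
#' @return `read_spectrum_library()`: validated library matrix (see
#'   [spectrum_library()]).
#' @export
read_spectrum_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "name")
    stop("spectrum library CSV must start with a 'name' column: ", path)
  if (ncol(df) - 1 != N_MZ)
    stop("spectrum library CSV must have ", N_MZ, " intensity columns, got ",
         ncol(df) - 1, ": ", path)
  if (!identical(names(df)[-1], mz_labels()))
    stop("intensity columns must be headed mz_50..mz_250 in order: ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric intensity column '", names(df)[-1][bad], "' in ", path)
  }
  spectrum_library(vals, names = as.character(df$name))
}

#' @rdname read_spectrum_library
#' @param lib Library matrix to write.
#' @export
write_spectrum_library <- function(lib, path) {
  validate_spectrum_library(lib)
  df <- data.frame(name = rownames(lib), lib, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write binary descriptor matrices as CSV
#'
#' Same dialect as the spectrum library: a `name` column followed by one
#' 0/1 column per descriptor, headed by the descriptor labels. The column
#' order read from disk is preserved as the vocabulary order.
#'
#' @param path Path to the CSV file.
#' @return `read_descriptor_matrix()`: a list with `vocabulary` (character
#'   vector, in file order) and `matrix` (validated 0/1 matrix).
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "name")
    stop("descriptor CSV must start with a 'name' column: ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  mat <- descriptor_matrix(vals, names = as.character(df$name))
  list(vocabulary = colnames(mat), matrix = mat)
}

#' @rdname read_descriptor_matrix
#' @param desc Descriptor matrix to write.
#' @export
write_descriptor_matrix <- function(desc, path) {
  validate_descriptor_matrix(desc)
  df <- data.frame(name = rownames(desc), desc, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import spectra from a NIST MSP text file
#'
#' Minimal read-only import of the MSP plain-text exchange format: records
#' begin with `Name:`, declare `Num Peaks:`, and list `m/z intensity` pairs
#' separated by whitespace or semicolons. Peaks are rounded to the nearest
#' integer m/z and accumulated onto the fixed 50-250 grid; peaks outside the
#' grid are dropped with a warning.
#'
#' @param path Path to an `.msp` file.
#' @return Spectrum library matrix (see [spectrum_library()]).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  axis <- mz_axis()
  specs <- list(); nm <- character()
  cur <- NULL; cur_name <- NULL; dropped <- 0L
  flush <- function() {
    if (!is.null(cur)) {
      specs[[length(specs) + 1L]] <<- cur
      nm[length(nm) + 1L] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush()
      cur_name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      cur <- numeric(N_MZ)
    } else if (grepl("^[A-Za-z]", ln)) {
      next  # other header fields (Num Peaks, MW, ...) are ignored
    } else if (!is.null(cur)) {
      toks <- strsplit(ln, "[;,]?[[:space:]]+|;")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) %% 2 != 0)
        stop("malformed peak line in ", path, ": '", ln, "'")
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) stop("non-numeric peak in ", path, ": '", ln, "'")
      mz <- round(vals[seq(1, length(vals), by = 2)])
      it <- vals[seq(2, length(vals), by = 2)]
      keep <- mz >= axis[1] & mz <= axis[N_MZ]
      dropped <- dropped + sum(!keep)
      idx <- mz[keep] - axis[1] + 1
      for (k in seq_along(idx)) cur[idx[k]] <- cur[idx[k]] + it[keep][k]
    }
  }
  flush()
  if (!length(specs)) stop("no MSP records found in ", path)
  if (dropped > 0)
    warning(dropped, " peak(s) outside m/z 50-250 dropped while reading ", path)
  spectrum_library(do.call(rbind, specs), names = nm)
}

#' Read and write recipes as JSON
#'
#' A recipe is stored as `{"components": [...], "ratios": [...],
#' "normalized": true/false}`.
#'
#' @param path Path to the JSON file.
#' @return `read_recipe()`: named numeric vector of mixing ratios.
#' @export
read_recipe <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- as.numeric(obj$ratios)
  if (!is.null(obj$components)) names(r) <- obj$components
  if (any(r < 0)) stop("recipe in ", path, " has negative ratios")
  r
}

#' @rdname read_recipe
#' @param recipe Non-negative numeric vector (names are component labels).
#' @export
write_recipe <- function(recipe, path) {
  obj <- list(
    components = if (is.null(names(recipe)))
      paste0("component_", seq_along(recipe)) else names(recipe),
    ratios = unname(recipe),
    normalized = isTRUE(all.equal(sum(recipe), 1, tolerance = 1e-12))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
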