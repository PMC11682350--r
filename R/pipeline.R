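#' Save and load an odor-component basis
#'
#' The basis is persisted as two CSVs (`W.csv`: oils x components;
#' `H.csv`: components x m/z bins) plus a JSON sidecar with K, seed, final
#' loss and iteration count.
#'
#' @param basis An `odor_basis`.
#' @param dir Directory to write into (created if needed).
#' @return `save_basis()`: the directory, invisibly. `load_basis()`: the
#'   restored `odor_basis`.
#' @export
save_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "odor_basis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(name = rownames(basis$W), basis$W,
                              check.names = FALSE, row.names = NULL),
                   file.path(dir, "W.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(component = rownames(basis$H), basis$H,
                              check.names = FALSE, row.names = NULL),
                   file.path(dir, "H.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(K = basis$K, seed = basis$seed,
                            fit_loss = basis$fit_loss, n_iter = basis$n_iter,
                            converged = basis$converged),
                       file.path(dir, "basis.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_basis
#' @export
load_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "basis.json"),
                              simplifyVector = TRUE)
  Wdf <- utils::read.csv(file.path(dir, "W.csv"), check.names = FALSE)
  Hdf <- utils::read.csv(file.path(dir, "H.csv"), check.names = FALSE)
  W <- as.matrix(Wdf[, -1, drop = FALSE]); rownames(W) <- Wdf[[1]]
  H <- as.matrix(Hdf[, -1, drop = FALSE]); rownames(H) <- Hdf[[1]]
  structure(list(W = W, H = H, K = as.integer(meta$K),
                 fit_loss = meta$fit_loss, loss_trace = numeric(0),
                 n_iter = as.integer(meta$n_iter),
                 converged = isTRUE(meta$converged),
                 seed = as.integer(meta$seed)),
            class = "odor_basis")
}

#' Save and load a trained predictor
#'
#' Weights, biases, vocabulary and the full configuration are written to a
#' single portable JSON file (numbers at full precision).
#'
#' @param predictor An `odor_predictor`.
#' @param path JSON file path.
#' @return `save_predictor()`: the path, invisibly. `load_predictor()`:
#'   the restored `odor_predictor`.
#' @export
save_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "odor_predictor"))
  obj <- list(config = unclass(predictor$config),
              vocabulary = predictor$vocabulary,
              loss_trace = predictor$loss_trace,
              W = lapply(predictor$W, function(w)
                list(dim = dim(w), data = as.vector(w))),
              b = predictor$b)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- lapply(obj$config, function(x) if (is.list(x)) unlist(x) else x)
  cfg$layer_sizes <- as.integer(cfg$layer_sizes)
  cfg$dropout <- vapply(obj$config$dropout,
                        function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                        numeric(1))
  class(cfg) <- "predictor_config"
  W <- lapply(obj$W, function(w)
    matrix(as.numeric(unlist(w$data)), nrow = as.integer(w$dim[[1]])))
  b <- lapply(obj$b, function(x) as.numeric(unlist(x)))
  structure(list(config = cfg, W = W, b = b,
                 vocabulary = as.character(unlist(obj$vocabulary)),
                 loss_trace = as.numeric(unlist(obj$loss_trace))),
            class = "odor_predictor")
}

#' Run the full design pipeline
#'
#' Fits (or loads) the odor-component basis, trains (or loads) the
#' descriptor predictor, runs the recipe search for a target descriptor
#' set, and writes the artifacts: `recipe.json`, `blend.csv` (per-oil
#' volumes), `loss_trace.csv`, and `manifest.json` recording every seed
#' and setting needed to reproduce the run. Any stage failure aborts with
#' the stage name and cause.
#'
#' @param library_path CSV spectrum library (see
#'   [read_spectrum_library()]).
#' @param descriptor_path CSV binary descriptor matrix.
#' @param target Named target: a named 0/1 vector over descriptor labels,
#'   or a path to a JSON object mapping labels to 0/1. Labels absent from
#'   the vocabulary are an error; vocabulary labels absent from the target
#'   default to 0.
#' @param out_dir Output directory.
#' @param nmf List of arguments for [fit_components()] (e.g. `K`, `seed`),
#'   or a directory to [load_basis()] from.
#' @param dnn A [predictor_config()], or a JSON path to
#'   [load_predictor()] from.
#' @param search A [search_config()].
#' @param volume Total blend volume for `blend.csv`.
#' @return Invisibly, a list with the fitted `basis`, `predictor` and the
#'   `recipe_search` result.
#' @export
run_pipeline <- function(library_path, descriptor_path, target, out_dir,
                         nmf = list(K = 20, seed = 1),
                         dnn = predictor_config(), search = search_config(),
                         volume = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  lib <- stage("read-library", read_spectrum_library(library_path))
  dm <- stage("read-descriptors", read_descriptor_matrix(descriptor_path))

  basis <- stage("fit-components",
                 if (is.character(nmf)) load_basis(nmf)
                 else do.call(fit_components, c(list(lib = lib), nmf)))
  predictor <- stage("train-dnn",
                     if (is.character(dnn)) load_predictor(dnn)
                     else train_predictor(lib, dm$matrix, dnn))

  tv <- stage("target", {
    if (is.character(target) && length(target) == 1 && file.exists(target))
      target <- unlist(jsonlite::read_json(target, simplifyVector = TRUE))
    bad <- setdiff(names(target), dm$vocabulary)
    if (length(bad)) stop("unknown descriptor label(s): ",
                          paste(bad, collapse = ", "))
    v <- stats::setNames(numeric(length(dm$vocabulary)), dm$vocabulary)
    v[names(target)] <- as.numeric(target)
    v
  })

  res <- stage("design-recipe",
               design_recipe(unname(tv), basis, predictor, search))

  stage("write-artifacts", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    r <- res$recipe_norm
    names(r) <- rownames(basis$H)
    write_recipe(r, file.path(out_dir, "recipe.json"))
    blend <- recipe_to_blend(res$recipe, basis, volume)
    utils::write.csv(data.frame(oil = names(blend), volume = unname(blend)),
                     file.path(out_dir, "blend.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(res$loss_trace),
                                loss = res$loss_trace),
                     file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(library = library_path, descriptors = descriptor_path,
           target = as.list(tv),
           nmf = if (is.character(nmf)) nmf else nmf,
           dnn_preset = if (is.character(dnn)) dnn else dnn$preset,
           dnn_seed = if (is.character(dnn)) NA else dnn$seed,
           search = unclass(search), volume = volume,
           loss = res$loss, sae = res$sae, iterations = res$iterations,
           converged = res$converged,
           package_version = as.character(utils::packageVersion("scentforge"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  })
  invisible(list(basis = basis, predictor = predictor, result = res))
}
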