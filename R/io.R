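#' Write a paired dataset to disk
#'
#' Datasets are stored in R's native serialization (RDS): a list with
#' `inputs` and `targets` (float arrays, N x 128 x 128 logical layout stored
#' as H x W x N), the train/val/test split, the sensor counts and a copy of
#' the generating configuration for provenance.
#'
#' @param dataset A `pat_dataset`.
#' @param path Output file path (conventionally `.rds`).
#' @param config Optional configuration list embedded for provenance.
#' @return `path`, invisibly.
#' @export
write_pat_dataset <- function(dataset, path, config = NULL) {
  stop_if(!inherits(dataset, "pat_dataset"), "not a pat_dataset")
  obj <- unclass(dataset)
  obj$config <- config
  saveRDS(obj, path)
  invisible(path)
}

#' Read and validate a paired dataset
#'
#' Validates presence of the `inputs`/`targets` keys, array shapes, and the
#' \[0,1\] value range before returning; malformed containers produce
#' descriptive errors naming the offending key.
#'
#' @param path File written by [write_pat_dataset()].
#' @param tol Tolerance for range validation.
#' @return A `pat_dataset`.
#' @export
read_pat_dataset <- function(path, tol = 1e-6) {
  stop_if(!file.exists(path), "no such file: ", path)
  obj <- readRDS(path)
  for (key in c("inputs", "targets")) {
    stop_if(is.null(obj[[key]]), "dataset is missing the '", key, "' key")
    stop_if(!is.numeric(obj[[key]]) || length(dim(obj[[key]])) != 3,
            "dataset key '", key, "' must be a numeric H x W x N array")
    rng <- range(obj[[key]])
    stop_if(rng[1] < -tol || rng[2] > 1 + tol,
            "dataset key '", key, "' has values outside [0, 1]")
  }
  stop_if(!identical(dim(obj$inputs), dim(obj$targets)),
          "'inputs' and 'targets' shapes differ")
  class(obj) <- "pat_dataset"
  obj
}

#' Number of image pairs in a dataset
#' @param dataset A `pat_dataset`.
#' @export
dataset_size <- function(dataset) dim(dataset$inputs)[3]

#' Export / import a single image as grayscale PNG
#'
#' Values are mapped linearly from \[0, 1\] to the writer's 8-bit range;
#' PNG export is intended for previews (datasets round-trip losslessly
#' through [write_pat_dataset()]).
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path PNG file path.
#' @return `read_png_image` returns the matrix; `write_png_image` the path.
#' @export
write_png_image <- function(img, path) {
  stop_if(!is.matrix(img), "img must be a matrix")
  stop_if(min(img) < -1e-9 || max(img) > 1 + 1e-9, "img values outside [0, 1]")
  png::writePNG(pmin(pmax(img, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' @rdname write_png_image
#' @export
read_png_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default end-to-end pipeline configuration (demo scale)
#'
#' Every randomized stage carries an explicit seed so reruns are
#' bit-reproducible.
#'
#' @export
default_run_config <- function() {
  list(
    n_scenes = 20L,
    vessels = 0.25,
    n_sensors = 50L,
    snr_db = c(40, 60),
    seed = 1L,
    width_factor = 20L,
    stage = "stage3_full",
    learning_rate = 1e-3,
    batch_size = 8L,
    epochs = 2L,
    out_dir = "sparsepat-run"
  )
}
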