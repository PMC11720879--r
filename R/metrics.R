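#' Image-quality metrics
#'
#' Pixelwise mean squared error, peak signal-to-noise ratio, structural
#' similarity and mean absolute error between a reconstruction `y` and a
#' ground truth `G`, as used to score sparse-view reconstructions.
#'
#' @param y,G Numeric matrices (or arrays) of identical shape.
#' @return A scalar.
#' @name metrics
NULL

check_same_shape <- function(y, G) {
  stop_if(!is.numeric(y) || !is.numeric(G), "images must be numeric")
  stop_if(!identical(dim(y), dim(G)) || length(y) != length(G),
          "image shapes differ")
}

#' @rdname metrics
#' @export
mse_metric <- function(y, G) {
  check_same_shape(y, G)
  mean((y - G)^2)
}

#' @rdname metrics
#' @details `psnr_metric` is `10 * log10(max(y, G)^2 / MSE)` in dB, where the
#'   maximum is taken over the values of both images; identical images have
#'   zero MSE and the function returns `Inf` to signal that distinctly.
#' @export
psnr_metric <- function(y, G) {
  check_same_shape(y, G)
  m <- mse_metric(y, G)
  if (m == 0) return(Inf)
  10 * log10(max(y, G)^2 / m)
}

#' @rdname metrics
#' @export
mae_metric <- function(y, G) {
  check_same_shape(y, G)
  mean(abs(y - G))
}

# population mean / variance / covariance SSIM kernel
ssim_formula <- function(muy, mug, vary, varg, covyg, c1, c2) {
  (2 * muy * mug + c1) * (2 * covyg + c2) /
    ((muy^2 + mug^2 + c1) * (vary + varg + c2))
}

#' @rdname metrics
#' @param mode `"windowed"` (default; mean of the SSIM map over sliding
#'   windows) or `"global"` (one window covering the whole image).
#' @param window Odd sliding-window side length.
#' @param constants `"literal"` uses the stabilization constants c1 = 0.01 and
#'   c2 = 0.03 directly; `"standard"` uses the conventional
#'   (k L)^2 values c1 = 1e-4, c2 = 9e-4 for unit dynamic range.
#' @details `ssim_metric` implements the luminance/contrast/structure
#'   product form with population (n-divisor) statistics. Identical images
#'   give exactly 1.
#' @export
ssim_metric <- function(y, G, mode = c("windowed", "global"), window = 7L,
                        constants = c("literal", "standard")) {
  check_same_shape(y, G)
  mode <- match.arg(mode)
  cc <- switch(match.arg(constants),
               literal = c(0.01, 0.03),
               standard = c(0.01^2, 0.03^2))
  if (mode == "global") {
    muy <- mean(y); mug <- mean(G)
    return(ssim_formula(muy, mug, mean((y - muy)^2), mean((G - mug)^2),
                        mean((y - muy) * (G - mug)), cc[1], cc[2]))
  }
  stop_if(window %% 2 != 1 || window < 3, "window must be odd and >= 3")
  stop_if(any(dim(y) < window), "image smaller than the SSIM window")
  r <- (window - 1L) %/% 2L
  box <- function(img) {
    x <- img
    dim(x) <- c(dim(img), 1L, 1L)
    k <- array(1 / window^2, c(window, window, 1L, 1L))
    m <- conv2d_fwd(x, k, 0, 1L, FALSE)[, , 1, 1]
    m[(r + 1):(nrow(m) - r), (r + 1):(ncol(m) - r)] # valid windows only
  }
  y <- as.matrix(y); G <- as.matrix(G)
  muy <- box(y); mug <- box(G)
  vary <- box(y * y) - muy^2
  varg <- box(G * G) - mug^2
  covyg <- box(y * G) - muy * mug
  mean(ssim_formula(muy, mug, vary, varg, covyg, cc[1], cc[2]))
}

#' Score a stack of reconstructions against ground truth
#'
#' Computes per-image SSIM, PSNR, MAE and MSE plus their aggregate mean and
#' standard deviation (population, n divisor).
#'
#' @param pred,target `H x W x N` arrays (or single matrices).
#' @param ssim_mode Passed to [ssim_metric()].
#' @return A `metrics_report`: list with `per_image` (data frame) and
#'   `summary` (mean and sd per metric).
#' @export
metrics_report <- function(pred, target, ssim_mode = "windowed") {
  if (is.matrix(pred)) dim(pred) <- c(dim(pred), 1L)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  check_same_shape(pred, target)
  n <- dim(pred)[3]
  stop_if(n == 0, "empty image stack")
  per <- data.frame(
    ssim = vapply(seq_len(n), function(i)
      ssim_metric(pred[, , i], target[, , i], mode = ssim_mode), 0),
    psnr = vapply(seq_len(n), function(i)
      psnr_metric(pred[, , i], target[, , i]), 0),
    mae = vapply(seq_len(n), function(i)
      mae_metric(pred[, , i], target[, , i]), 0),
    mse = vapply(seq_len(n), function(i)
      mse_metric(pred[, , i], target[, , i]), 0)
  )
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    per_image = per,
    summary = data.frame(metric = names(per),
                         mean = vapply(per, mean, 0),
                         sd = vapply(per, sd_pop, 0),
                         row.names = NULL)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d images\n", nrow(x$per_image)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Evaluate a trained network on a test set
#'
#' @param model A `msdnet`.
#' @param inputs,targets `H x W x N` arrays.
#' @param ... Passed to [metrics_report()].
#' @return A `metrics_report`.
#' @export
evaluate_network <- function(model, inputs, targets, ...) {
  if (is.matrix(inputs)) dim(inputs) <- c(dim(inputs), 1L)
  stop_if(length(inputs) == 0 || dim(inputs)[3] == 0, "empty test set")
  metrics_report(predict(model, inputs), targets, ...)
}
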