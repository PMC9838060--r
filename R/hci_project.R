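# Z projection and illumination correction.

#' Maximum-intensity projection of a channel stack
#'
#' Sparse bright nuclei survive a maximum projection regardless of which Z
#' plane they focus in, which is why the pipeline projects before
#' segmenting.
#'
#' @param stack A [channel_stack()].
#' @return Named list of 2-d matrices, one per channel.
#' @export
project_stack <- function(stack) {
  lapply(stack$channels, function(ch) {
    if (dim(ch)[3] == 1L) return(ch[, , 1])
    apply(ch, c(1, 2), max)
  })
}

#' Pseudo-flatfield correction
#'
#' Divides the image by a heavily smoothed copy of itself (the
#' pseudo-flatfield), then rescales so the mean intensity is preserved.
#' Removes slowly varying illumination such as vignetting while leaving
#' object-scale structure intact. Output is non-negative; smoothed values
#' are floored at a small epsilon before division.
#'
#' @param image 2-d numeric matrix.
#' @param sigma Gaussian sigma (px) of the background estimate; should be
#'   much larger than the objects of interest (default 50).
#' @return Corrected matrix with the same dimensions and mean.
#' @export
flatfield_correct <- function(image, sigma = 50) {
  if (!is.matrix(image) || !length(image))
    stop_pq("image must be a non-empty matrix", class = "protoquant_input_error")
  bg <- gaussian_smooth(image, sigma)
  eps <- max(mean(bg) * 1e-6, .Machine$double.eps)
  out <- image / pmax(bg, eps)
  m <- mean(out)
  if (m > 0) out <- out * (mean(image) / m)
  pmax(out, 0)
}

# Separable Gaussian smoothing with replicated-edge padding. EBImage's
# filter2 is FFT-based (circular boundary), which bleeds opposite edges
# into each other -- exactly what a background estimate must not do, hence
# this small direct implementation.
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  sm_rows <- apply_kernel_1d(image, k)           # along rows (dim 1)
  t(apply_kernel_1d(t(sm_rows), k))              # along columns
}

apply_kernel_1d <- function(image, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(image)
  padded <- rbind(image[rep(1L, half), , drop = FALSE],
                  image,
                  image[rep(n, half), , drop = FALSE])
  out <- matrix(0, n, ncol(image))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  out
}
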