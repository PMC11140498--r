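#' Augmentation configuration for student noising
#'
#' The student is noised with two families of augmentation: a three-way
#' contrast adjustment (power-law transform, logarithmic correction, or no
#' change, each drawn with equal probability by default) applied to the image
#' only, and independent rescaling of head length and width applied to image
#' and mask congruently.
#'
#' @param mode_probs probabilities for the contrast modes
#'   `c(power, log, none)`; must sum to 1.
#' @param gamma_range range of the power-law exponent.
#' @param gain gain of the logarithmic correction; 1 maps [0,1] onto [0,1].
#' @param scale_x_range,scale_y_range multiplicative ranges for head width
#'   (columns) and length (rows).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(mode_probs = c(1, 1, 1) / 3,
                           gamma_range = c(0.5, 1.5),
                           gain = 1,
                           scale_x_range = c(0.85, 1.15),
                           scale_y_range = c(0.85, 1.15)) {
  if (length(mode_probs) != 3L || any(mode_probs < 0) ||
      abs(sum(mode_probs) - 1) > 1e-8)
    stop("'mode_probs' must be 3 nonnegative probabilities summing to 1")
  for (r in list(gamma_range, scale_x_range, scale_y_range))
    if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
      stop("ranges must be positive, ordered, length-2")
  if (gain <= 0) stop("'gain' must be positive")
  structure(list(mode_probs = mode_probs, gamma_range = gamma_range,
                 gain = gain, scale_x_range = scale_x_range,
                 scale_y_range = scale_y_range),
            class = "augment_config")
}

#' Power-law (gamma) contrast transform
#'
#' @param image numeric matrix with values in [0, 1].
#' @param gamma positive exponent; `image^gamma` elementwise.
#' @return Transformed image, same shape, values in [0, 1].
#' @export
power_law <- function(image, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  image^gamma
}

#' Logarithmic contrast correction
#'
#' `gain * log2(1 + image)`; with `gain = 1` this maps the unit interval onto
#' itself monotonically (log2(2) = 1), brightening dark regions.
#'
#' @param image numeric matrix with values in [0, 1].
#' @param gain positive gain.
#' @return Transformed image, same shape.
#' @export
log_correction <- function(image, gain = 1) {
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("'gain' must be a positive scalar")
  gain * log2(1 + image)
}

#' Draw one contrast-augmentation mode
#'
#' @param config an [augment_config()].
#' @return One of `"power"`, `"log"`, `"none"`.
#' @export
sample_contrast_mode <- function(config) {
  stopifnot(inherits(config, "augment_config"))
  c("power", "log", "none")[sample.int(3L, 1L, prob = config$mode_probs)]
}

#' Rescale head length and width
#'
#' Rescales image content by `sy` along rows and `sx` along columns about the
#' image center, then center-crops/pads back to the original shape. The image
#' is interpolated bilinearly; the mask is transformed with nearest-neighbor
#' sampling so it stays binary. Image and mask undergo the identical
#' geometric map.
#'
#' @param image numeric matrix.
#' @param mask integer matrix of the same shape (may be tri-state).
#' @param sx,sy positive scale factors for columns (width) and rows (length).
#' @param background fill value for pixels mapped from outside the source.
#' @return List with transformed `image` and `mask`.
#' @export
rescale_head <- function(image, mask, sx, sy, background = 0.05) {
  if (sx <= 0 || sy <= 0) stop("scale factors must be positive")
  stopifnot(all(dim(image) == dim(mask)))
  if (sx == 1 && sy == 1) return(list(image = image, mask = mask))
  nr <- nrow(image); nc <- ncol(image)
  # inverse map: output pixel (r, c) pulls from source ((r-cr)/sy+cr, (c-cc)/sx+cc)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  src_r <- (seq_len(nr) - cr) / sy + cr
  src_c <- (seq_len(nc) - cc) / sx + cc

  # bilinear for the image
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  clampr <- function(i) pmin(pmax(i, 1L), nr)
  clampc <- function(i) pmin(pmax(i, 1L), nc)
  inside_r <- src_r >= 1 & src_r <= nr
  inside_c <- src_c >= 1 & src_c <= nc
  ir0 <- clampr(r0); ir1 <- clampr(r0 + 1)
  ic0 <- clampc(c0); ic1 <- clampc(c0 + 1)
  w00 <- outer(1 - fr, 1 - fc); w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc); w11 <- outer(fr, fc)
  out <- image[ir0, ic0] * w00 + image[ir0, ic1] * w01 +
         image[ir1, ic0] * w10 + image[ir1, ic1] * w11
  out[!inside_r, ] <- background
  out[, !inside_c] <- background

  # nearest-neighbor for the mask, same inverse map
  nn_r <- clampr(as.integer(round(src_r)))
  nn_c <- clampc(as.integer(round(src_c)))
  mout <- mask[nn_r, nn_c]
  mout[!inside_r, ] <- 0L
  mout[, !inside_c] <- 0L
  storage.mode(mout) <- "integer"
  list(image = out, mask = mout)
}

#' Apply one random augmentation draw to a training sample
#'
#' Draws a contrast mode and applies it to the image only (pixel labels are
#' geometric, not photometric), then draws independent width/length scales
#' and applies [rescale_head()] to both image and mask. Deterministic given
#' the RNG state.
#'
#' @param image numeric matrix in [0, 1].
#' @param mask integer matrix, binary or tri-state.
#' @param config an [augment_config()].
#' @return List with augmented `image` and `mask`.
#' @export
augment_sample <- function(image, mask, config) {
  stopifnot(inherits(config, "augment_config"))
  mode <- sample_contrast_mode(config)
  if (mode == "power") {
    gamma <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
    image <- power_law(image, gamma)
  } else if (mode == "log") {
    image <- log_correction(image, config$gain)
  }
  sx <- stats::runif(1, config$scale_x_range[1], config$scale_x_range[2])
  sy <- stats::runif(1, config$scale_y_range[1], config$scale_y_range[2])
  rescale_head(image, mask, sx, sy)
}
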