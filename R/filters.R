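# Homomorphic and anti-homomorphic frequency-domain enhancement, plus the
# four spatial baseline filters (4- and 8-neighbour Laplacian sharpening,
# Gaussian, bilateral).
#
# The homomorphic filter linearises the multiplicative illumination x
# reflectance model with a logarithm, applies a radial high-frequency
# emphasis gain in the centered frequency domain, and exponentiates back.
# Its anti-homomorphic dual runs the pipeline the other way around: the
# dynamic range is first EXPANDED by the exponential, linear filtering is
# applied with the INVERTED gain, and the logarithm compresses the range
# back.  For unit gain both reduce to the identity.

#' High-frequency-emphasis gain function
#'
#' Builds the radial gain grid
#' \deqn{H(u,v) = (\gamma_H - \gamma_L)\,(1 - e^{-c\,D^2(u,v)/d_0^2}) + \gamma_L}
#' with \eqn{D} the centered radial frequency in cycles/pixel (Nyquist at
#' 0.5).  At the spectrum centre \eqn{H = \gamma_L}; far from it
#' \eqn{H \to \gamma_H}.  With \eqn{\gamma_L < 1 < \gamma_H} the gain
#' attenuates illumination (low frequencies) and amplifies reflectance
#' detail (high frequencies).
#'
#' @param shape integer pair `c(height, width)`.
#' @param gamma_low low-frequency gain, > 0.
#' @param gamma_high high-frequency gain, > 0.
#' @param c_sharp sharpness constant controlling the transition slope.
#' @param d0 cutoff radius in cycles/pixel (> 0); default 0.1, i.e. a fifth
#'   of the Nyquist radius.
#' @return an object of class `gain_function` with the evaluated grid in
#'   `$values` (all entries strictly positive, so the inverted gain exists).
#' @export
make_emphasis_gain <- function(shape, gamma_low = 0.5, gamma_high = 2.0,
                               c_sharp = 1, d0 = 0.1) {
  if (gamma_low <= 0 || gamma_high <= 0) {
    stop("gamma_low and gamma_high must be positive")
  }
  if (d0 <= 0) stop("d0 must be positive")
  stopifnot(length(shape) == 2, all(shape >= 1))
  D <- radial_frequency_grid(shape[1], shape[2])
  H <- (gamma_high - gamma_low) * (1 - exp(-c_sharp * D^2 / d0^2)) + gamma_low
  structure(list(values = H,
                 gamma_low = gamma_low, gamma_high = gamma_high,
                 c_sharp = c_sharp, d0 = d0,
                 shape = as.integer(shape)),
            class = "gain_function")
}

gain_values <- function(gain) {
  if (inherits(gain, "gain_function")) gain$values
  else if (is.matrix(gain)) gain
  else stop("gain must be a gain_function or a numeric matrix")
}

#' Homomorphic filter
#'
#' `exp( IFT( H . FT( ln(img + eps) ) ) ) - eps`, optionally min-max
#' normalised so outputs of different filters are comparable.
#'
#' @param img image matrix in `[0, 1]`.
#' @param gain a [make_emphasis_gain()] object (or bare gain matrix) of the
#'   same shape.
#' @param eps positive guard added before the logarithm (default `1e-6`).
#' @param normalize min-max normalise the output to `[0, 1]` (default TRUE).
#' @return filtered image matrix.
#' @export
homomorphic_filter <- function(img, gain, eps = 1e-6, normalize = TRUE) {
  check_image(img)
  H <- gain_values(gain)
  if (!identical(dim(img), dim(H))) stop("gain shape must match the image")
  if (eps <= 0) stop("eps must be positive")
  z <- log(img + eps)
  s <- Re(ifft2_centered(H * fft2_centered(z)))
  out <- exp(s) - eps
  if (normalize) minmax_normalize(out) else out
}

#' Anti-homomorphic filter
#'
#' The dual pipeline: the exponential first expands the dynamic range to
#' recover linear-domain intensities, the INVERTED gain `1/H` is applied in
#' the frequency domain, and the logarithm compresses the range back:
#' `ln( max(IFT( (1/H) . FT( exp(img) ) ), eps) )`.  Requires a strictly
#' positive gain everywhere.
#'
#' @inheritParams homomorphic_filter
#' @return filtered image matrix.
#' @export
anti_homomorphic_filter <- function(img, gain, eps = 1e-6, normalize = TRUE) {
  check_image(img)
  H <- gain_values(gain)
  if (!identical(dim(img), dim(H))) stop("gain shape must match the image")
  if (eps <= 0) stop("eps must be positive")
  if (any(H <= 0)) stop("anti-homomorphic filter requires a strictly positive gain")
  e <- exp(img)
  s <- Re(ifft2_centered((1 / H) * fft2_centered(e)))
  out <- log(pmax(s, eps))
  if (normalize) minmax_normalize(out) else out
}

#' Baseline spatial enhancement filters
#'
#' The four comparison filters: `lf4c`/`lf8c` subtract the 4-/8-neighbour
#' Laplacian response from the image (unsharp-style edge sharpening), `gf`
#' is Gaussian smoothing, `blf` is bilateral smoothing (Gaussian spatial
#' kernel weighted by a Gaussian range kernel, so edges are preserved).
#' All outputs are clipped to `[0, 1]`.
#'
#' @param img image matrix in `[0, 1]`.
#' @param method one of `"lf4c"`, `"lf8c"`, `"gf"`, `"blf"`.
#' @param sigma Gaussian spatial standard deviation in pixels (for `gf`,
#'   `blf`).
#' @param sigma_r bilateral range standard deviation in intensity units
#'   (for `blf`).
#' @param window odd bilateral window width in pixels (for `blf`).
#' @return filtered image matrix in `[0, 1]`.
#' @export
baseline_enhance <- function(img, method, sigma = 1, sigma_r = 0.1,
                             window = 5L) {
  check_image(img)
  valid <- c("lf4c", "lf8c", "gf", "blf")
  if (!is.character(method) || length(method) != 1 || !(method %in% valid)) {
    stop("unknown method; valid methods: ", paste(valid, collapse = ", "))
  }
  out <- switch(method,
    lf4c = img - conv2_full(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)),
    lf8c = img - conv2_full(img, matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)),
    gf = conv_separable(img, gaussian_kernel(sigma)),
    blf = bilateral_filter(img, sigma, sigma_r, window)
  )
  clip01(out)
}

# Brute-ish bilateral: loop over window offsets, vectorised over pixels.
bilateral_filter <- function(img, sigma_s, sigma_r, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  for (dr in -half:half) {
    for (dc in -half:half) {
      ws <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
      shifted <- shift_matrix(img, dr, dc, fill = NA)
      w <- ws * exp(-(shifted - img)^2 / (2 * sigma_r^2))
      w[is.na(shifted)] <- 0
      shifted[is.na(shifted)] <- 0
      num <- num + w * shifted
      den <- den + w
    }
  }
  num / den
}
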