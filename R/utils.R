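# Shared numeric helpers: clipping, normalisation, centered 2-D transforms,
# separable convolution.  Images throughout the package are plain numeric
# matrices with intensities in [0, 1], row 1 at the top (0-based (row, col)
# coordinates in all user-facing geometry arguments).

#' Clip a numeric array into an interval
#'
#' @param x numeric vector/matrix.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clip01 <- function(x, lo = 0, hi = 1) {
  pmin(pmax(x, lo), hi)
}

#' Min-max normalise to \[0, 1\]
#'
#' Constant inputs are returned unchanged (there is no contrast to stretch).
#'
#' @param x numeric matrix.
#' @return matrix with minimum 0 and maximum 1 (unless constant).
#' @export
minmax_normalize <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("minmax_normalize: non-finite values")
  if (rng[2] - rng[1] <= 0) return(x)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Validate an image matrix
#' @param img numeric matrix, intensities expected in \[0, 1\].
#' @keywords internal
check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix")
  }
  if (any(!is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}

# Swap quadrants so the zero-frequency bin sits at the grid centre
# (position floor(n/2) + 1 along each axis), and the inverse swap.
fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(floor(h / 2) + 1, h), seq_len(floor(h / 2))),
    c(seq(floor(w / 2) + 1, w), seq_len(floor(w / 2)))]
}

ifftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(ceiling(h / 2) + 1, h), seq_len(ceiling(h / 2))),
    c(seq(ceiling(w / 2) + 1, w), seq_len(ceiling(w / 2)))]
}

#' Centered 2-D discrete Fourier transform
#'
#' Forward transform with the zero-frequency component moved to the grid
#' centre, so radial gain functions are literal distance functions of the
#' spectrum layout.
#'
#' @param x real or complex matrix.
#' @return complex matrix of the same shape.
#' @export
fft2_centered <- function(x) {
  fftshift2(stats::fft(x))
}

#' Inverse of [fft2_centered()]
#'
#' @param X complex matrix with zero-frequency at the centre.
#' @return complex matrix; take `Re()` for real signals.
#' @export
ifft2_centered <- function(X) {
  stats::fft(ifftshift2(X), inverse = TRUE) / length(X)
}

# Centered radial frequency grid in cycles/pixel: along each axis the
# frequencies run from -floor(n/2)/n to (ceiling(n/2)-1)/n, so the Nyquist
# magnitude is 0.5.  Returns the matrix D(u, v) = sqrt(u^2 + v^2) laid out
# to match fft2_centered().
radial_frequency_grid <- function(height, width) {
  fu <- (seq_len(height) - 1 - floor(height / 2)) / height
  fv <- (seq_len(width) - 1 - floor(width / 2)) / width
  sqrt(outer(fu^2, fv^2, `+`))
}

# Separable 2-D convolution with a symmetric 1-D kernel, replicate padding
# at the borders (so constants are exact fixed points of smoothing kernels
# that sum to one).
conv_separable <- function(img, kernel) {
  k <- length(kernel)
  if (k == 1L) return(img * kernel)
  half <- (k - 1L) %/% 2L
  pad_idx <- function(n) clip01(seq(1 - half, n + half), 1, n)
  # rows
  ri <- pad_idx(nrow(img))
  tmp <- matrix(0, nrow(img), ncol(img))
  for (j in seq_len(k)) {
    tmp <- tmp + kernel[j] * img[ri[seq_len(nrow(img)) + (j - 1L)], , drop = FALSE]
  }
  ci <- pad_idx(ncol(img))
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_len(k)) {
    out <- out + kernel[j] * tmp[, ci[seq_len(ncol(img)) + (j - 1L)], drop = FALSE]
  }
  out
}

# Discrete Gaussian kernel truncated at 4*sigma, normalised to sum 1.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# 2-D convolution with an arbitrary small kernel (odd dimensions),
# replicate padding.  Used by the Laplacian baselines.
conv2_full <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  ri <- clip01(seq(1 - hh, n + hh), 1, n)
  ci <- clip01(seq(1 - hw, m + hw), 1, m)
  out <- matrix(0, n, m)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kernel[a, b] == 0) next
      out <- out + kernel[a, b] *
        img[ri[seq_len(n) + (a - 1L)], ci[seq_len(m) + (b - 1L)], drop = FALSE]
    }
  }
  out
}

# Shift a matrix by integer offsets, filling vacated cells with `fill`.
shift_matrix <- function(x, dr, dc, fill = 0) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  src_r <- seq_len(n) - dr
  src_c <- seq_len(m) - dc
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Two-level lesion-candidate extraction: a first Otsu split isolates the
# bright (head) compartment, a second Otsu within it isolates the
# brightest structures (lesion candidates).
lesion_candidates <- function(img) {
  t1 <- otsu_threshold(img)
  bright <- img[img > t1]
  if (length(bright) < 2) return(img > t1)
  img > otsu_threshold(matrix(bright, nrow = 1))
}

# Otsu's threshold on a [0,1] image using a fixed 256-bin histogram.
otsu_threshold <- function(img, nbins = 256L) {
  check_image(img)
  h <- tabulate(pmin(pmax(floor(img * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nbins) - 0.5) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}
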