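# Synthetic neonatal-brain MR slice generator.  Emulates the salient
# properties of diffusion MR slices of term neonates with hypoxic-ischemic
# injury: 256x256 grayscale, an elliptical head with grey/white tissue
# bands, small multi-focal low-contrast lesions dispersed through tissue,
# and the three artifact families targeted by the enhancement pipeline
# (partial-volume blur, chemical-shift bright/dark bands, motion ghosting).

#' Phantom generation parameters
#'
#' @param height,width slice size in pixels.
#' @param lesion_count_range integer interval `c(min, max)` for the number
#'   of lesion foci drawn (uniformly) per slice.
#' @param lesion_radius_range lesion disk radius interval in pixels.
#' @param lesion_contrast intensity delta added to tissue under each lesion,
#'   in `[0, 1]`.  Lesions are deliberately low-contrast.
#' @param tissue_levels named or unnamed triplet of background / grey-matter /
#'   white-matter intensities, each in `[0, 1]`.
#' @param pv_sigma partial-volume blur standard deviation in pixels.
#' @param cs_shift chemical-shift displacement of the fat compartment in
#'   pixels (integer).
#' @param cs_axis axis of the chemical-shift displacement, `"row"` or `"col"`
#'   (the readout direction).
#' @param ghost_amplitude motion-ghosting modulation amplitude in `[0, 1]`.
#' @param ghost_interval every `ghost_interval`-th k-space line is modulated
#'   (integer, at least 2).
#' @param seed integer seed; a fixed seed yields bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         lesion_count_range = c(0L, 20L),
                         lesion_radius_range = c(2, 6),
                         lesion_contrast = 0.18,
                         tissue_levels = c(background = 0.05,
                                           grey = 0.45, white = 0.62),
                         pv_sigma = 1.0,
                         cs_shift = 3L,
                         cs_axis = c("col", "row"),
                         ghost_amplitude = 0.25,
                         ghost_interval = 8L,
                         seed = 1L) {
  cs_axis <- match.arg(cs_axis)
  stopifnot(height >= 16, width >= 16)
  if (length(lesion_count_range) != 2 ||
      lesion_count_range[1] > lesion_count_range[2] ||
      lesion_count_range[1] < 0) {
    stop("lesion_count_range must be a non-empty non-negative interval")
  }
  if (length(lesion_radius_range) != 2 ||
      lesion_radius_range[1] > lesion_radius_range[2] ||
      lesion_radius_range[1] < 1) {
    stop("lesion_radius_range must be a non-empty interval with radii >= 1")
  }
  if (lesion_contrast < 0 || lesion_contrast > 1) {
    stop("lesion_contrast must lie in [0, 1]")
  }
  if (length(tissue_levels) != 3 || any(tissue_levels < 0) ||
      any(tissue_levels > 1)) {
    stop("tissue_levels must be three intensities in [0, 1]")
  }
  if (pv_sigma < 0) stop("pv_sigma must be non-negative")
  if (ghost_amplitude < 0 || ghost_amplitude > 1) {
    stop("ghost_amplitude must lie in [0, 1]")
  }
  if (ghost_interval < 2) stop("ghost_interval must be at least 2")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_contrast = lesion_contrast,
    tissue_levels = stats::setNames(as.numeric(tissue_levels),
                                    c("background", "grey", "white")),
    pv_sigma = pv_sigma,
    cs_shift = as.integer(cs_shift), cs_axis = cs_axis,
    ghost_amplitude = ghost_amplitude,
    ghost_interval = as.integer(ghost_interval),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Elliptical mask: centre (cr, cc), semi-axes (ar, ac), 1-based row/col grid.
ellipse_mask <- function(height, width, cr, cc, ar, ac) {
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - cr) / ar)^2 + ((c_ - cc) / ac)^2 <= 1
}

disk_mask <- function(height, width, cr, cc, radius) {
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  (r - cr)^2 + (c_ - cc)^2 <= radius^2
}

#' Stage label from lesion burden
#'
#' The stage is a deterministic function of the lesion-area fraction of the
#' head region: below 0.5\% mild, 0.5--2\% moderate, above 2\% severe.
#'
#' @param lesion_area lesion pixel count.
#' @param head_area head-region pixel count.
#' @return one of `"mild"`, `"moderate"`, `"severe"`.
#' @export
stage_from_burden <- function(lesion_area, head_area) {
  frac <- lesion_area / head_area
  if (frac < 0.005) "mild" else if (frac <= 0.02) "moderate" else "severe"
}

#' Stage labels
#' @return the ordered stage vocabulary.
#' @export
stage_levels <- function() c("mild", "moderate", "severe")

#' Generate one synthetic slice
#'
#' Draws a clean slice (elliptical head with a grey-matter rim and
#' white-matter interior, multi-focal lesion disks of elevated intensity)
#' and then applies, in order, partial-volume blur, chemical shift of the
#' scalp-fat rim, and motion ghosting, each controlled by the spec.
#' Lesion centres are rejection-sampled uniformly inside the white-matter
#' region and may not overlap an existing lesion.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_sample` list with elements `image` (artifacted slice),
#'   `clean` (pre-artifact slice), `lesion_mask`, `artifact_mask` (pixels
#'   materially changed by the artifact stack), `head_mask`, `fat_mask`,
#'   and `stage`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  set.seed(spec$seed)

  cr <- h / 2; cc <- w / 2
  ar <- 0.44 * h; ac <- 0.38 * w
  head <- ellipse_mask(h, w, cr, cc, ar, ac)
  # fat rim: between the head ellipse and a slightly shrunk inner ellipse
  inner <- ellipse_mask(h, w, cr, cc, 0.95 * ar, 0.95 * ac)
  white <- ellipse_mask(h, w, cr, cc, 0.80 * ar, 0.80 * ac)

  lv <- spec$tissue_levels
  img <- matrix(lv[["background"]], h, w)
  img[head] <- lv[["grey"]]
  img[white] <- lv[["white"]]
  fat <- head & !inner

  max_r <- spec$lesion_radius_range[2]
  if (max_r >= min(0.80 * ar, 0.80 * ac)) {
    stop("lesion_radius_range: maximum radius ", max_r,
         " does not fit inside the head region")
  }

  n_les <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2]) {
    spec$lesion_count_range[1]
  } else {
    sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1L)
  }
  lesion_mask <- matrix(FALSE, h, w)
  placed <- 0L
  attempts <- 0L
  while (placed < n_les && attempts < 2000L) {
    attempts <- attempts + 1L
    rad <- stats::runif(1, spec$lesion_radius_range[1],
                        spec$lesion_radius_range[2])
    lr <- stats::runif(1, 1, h)
    lc <- stats::runif(1, 1, w)
    d <- disk_mask(h, w, lr, lc, rad)
    if (!all(white[d])) next          # keep foci inside white matter
    if (any(lesion_mask & d)) next    # disallow overlap
    lesion_mask <- lesion_mask | d
    img[d] <- img[d] + spec$lesion_contrast
    placed <- placed + 1L
  }
  img <- clip01(img)
  clean <- img

  out <- apply_partial_volume(img, spec$pv_sigma)
  out <- apply_chemical_shift(out, fat, spec$cs_shift, spec$cs_axis)
  out <- apply_motion_ghosting(out, spec$ghost_amplitude, spec$ghost_interval)

  artifact_mask <- (abs(out - clean) > 0.02) & !lesion_mask

  structure(list(
    image = out,
    clean = clean,
    lesion_mask = lesion_mask,
    artifact_mask = artifact_mask,
    head_mask = head,
    fat_mask = fat,
    stage = stage_from_burden(sum(lesion_mask), sum(head))
  ), class = "phantom_sample")
}

#' Partial-volume artifact: Gaussian mixing of adjacent-tissue signal
#'
#' Voxels at tissue interfaces carry a mixture of the neighbouring signals;
#' this is modelled as an isotropic Gaussian low-pass of the slice.
#'
#' @param img image matrix in `[0, 1]`.
#' @param sigma blur standard deviation in pixels (`sigma = 0` is identity).
#' @return blurred image; intensity range stays inside `[0, 1]`.
#' @export
apply_partial_volume <- function(img, sigma) {
  check_image(img)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(img)
  clip01(conv_separable(img, gaussian_kernel(sigma)))
}

#' Chemical-shift artifact: displaced fat signal
#'
#' The fat resonance is offset from water, so the fat compartment is imaged
#' displaced by a few pixels along the readout axis.  The fat signal is
#' translated by `shift` and re-summed with the water signal, producing a
#' bright band where fat piles onto water and a dark band where it vacated.
#'
#' @param img image matrix in `[0, 1]`.
#' @param fat_mask logical matrix marking the fat compartment.
#' @param shift integer displacement in pixels (may be negative; 0 is
#'   identity).
#' @param axis `"row"` or `"col"`: the readout axis.
#' @return artifacted image clipped to `[0, 1]`.
#' @export
apply_chemical_shift <- function(img, fat_mask, shift, axis = c("col", "row")) {
  check_image(img)
  axis <- match.arg(axis)
  if (!identical(dim(img), dim(fat_mask))) {
    stop("fat_mask shape must match the image")
  }
  extent <- if (axis == "row") nrow(img) else ncol(img)
  if (abs(shift) >= extent) {
    stop("|shift| must be smaller than the image extent along ", axis)
  }
  if (shift == 0 || !any(fat_mask)) return(img)
  fat_sig <- img * fat_mask
  water_sig <- img * !fat_mask
  moved <- if (axis == "row") shift_matrix(fat_sig, shift, 0L)
           else shift_matrix(fat_sig, 0L, shift)
  clip01(water_sig + moved)
}

#' Motion-ghosting artifact: periodic k-space modulation
#'
#' Quasi-periodic subject motion modulates every `interval`-th phase-encode
#' line of k-space; here every `interval`-th row of the centered 2-D
#' spectrum is multiplied by `1 + amplitude`, and the magnitude of the
#' inverse transform is returned.  Ghost replicas appear at a spacing of
#' `height / interval` rows.
#'
#' @param img image matrix in `[0, 1]`.
#' @param amplitude modulation amplitude in `[0, 1]` (0 is identity up to
#'   transform round-off).
#' @param interval modulate every `interval`-th line; integer, at least 2.
#' @return real, finite, `[0, 1]`-clipped image.
#' @export
apply_motion_ghosting <- function(img, amplitude, interval) {
  check_image(img)
  if (amplitude < 0 || amplitude > 1) stop("amplitude must lie in [0, 1]")
  if (interval < 2) stop("interval must be at least 2")
  spec <- fft2_centered(img)
  rows <- seq(1L, nrow(img), by = as.integer(interval))
  rows <- rows[rows != floor(nrow(img) / 2) + 1L]  # spare the DC line: the
  # modulation models periodic phase-encode errors, not a brightness shift
  spec[rows, ] <- spec[rows, ] * (1 + amplitude)
  clip01(Mod(ifft2_centered(spec)))
}

# Geometric transforms used for augmentation.  All operate on integer grids
# and are applied identically to the image and its masks.
flip_h <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
flip_v <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]

translate_grid <- function(x, dr, dc, fill) shift_matrix(x, dr, dc, fill)

# Nearest-neighbour rescale about the image centre by factor s, same shape.
scale_grid <- function(x, s, fill) {
  n <- nrow(x); m <- ncol(x)
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  src_r <- round(cr + (seq_len(n) - cr) / s)
  src_c <- round(cc + (seq_len(m) - cc) / s)
  out <- matrix(fill, n, m)
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

apply_geom <- function(x, tr, fill = 0) {
  switch(tr$kind,
    identity = x,
    flip_h = flip_h(x),
    flip_v = flip_v(x),
    translate = translate_grid(x, tr$dr, tr$dc, fill),
    scale = scale_grid(x, tr$s, fill),
    stop("unknown transform kind: ", tr$kind)
  )
}

#' Augment a phantom dataset by translation, scaling, and flipping
#'
#' New samples are produced by applying one randomly chosen geometric
#' transform (integer translation up to +-10\% of each extent, scaling in
#' `[0.9, 1.1]` with nearest-neighbour mask resampling, or a horizontal or
#' vertical flip) to a randomly chosen base sample; the identical transform
#' is applied to the lesion and head masks and the stage label is
#' recomputed from the transformed masks.
#'
#' @param samples non-empty list of `phantom_sample` objects.
#' @param n_target total number of samples required
#'   (`n_target >= length(samples)`); the originals are always retained.
#' @param seed integer seed controlling base/transform draws.
#' @return list of exactly `n_target` samples; augmented samples carry a
#'   `transform` element describing their provenance.
#' @export
augment_dataset <- function(samples, n_target, seed = 1L) {
  if (length(samples) == 0) stop("augment_dataset: empty input list")
  if (n_target < length(samples)) {
    stop("n_target must be at least the number of input samples")
  }
  if (n_target == length(samples)) return(samples)
  set.seed(as.integer(seed))
  out <- samples
  bg <- 0
  for (i in seq_len(n_target - length(samples))) {
    base <- samples[[sample.int(length(samples), 1L)]]
    kind <- sample(c("translate", "scale", "flip_h", "flip_v"), 1L)
    tr <- switch(kind,
      translate = list(kind = "translate",
                       dr = sample.int(2L * round(0.1 * nrow(base$image)) + 1L, 1L) -
                            round(0.1 * nrow(base$image)) - 1L,
                       dc = sample.int(2L * round(0.1 * ncol(base$image)) + 1L, 1L) -
                            round(0.1 * ncol(base$image)) - 1L),
      scale = list(kind = "scale", s = stats::runif(1, 0.9, 1.1)),
      flip_h = list(kind = "flip_h"),
      flip_v = list(kind = "flip_v")
    )
    img <- apply_geom(base$image, tr, fill = bg)
    lm_ <- apply_geom(base$lesion_mask, tr, fill = FALSE) > 0
    hm <- apply_geom(base$head_mask, tr, fill = FALSE) > 0
    am <- apply_geom(base$artifact_mask, tr, fill = FALSE) > 0
    s <- structure(list(
      image = img,
      clean = apply_geom(base$clean, tr, fill = bg),
      lesion_mask = lm_,
      artifact_mask = am,
      head_mask = hm,
      fat_mask = apply_geom(base$fat_mask, tr, fill = FALSE) > 0,
      stage = stage_from_burden(sum(lm_), max(1L, sum(hm))),
      transform = tr
    ), class = "phantom_sample")
    out[[length(samples) + i]] <- s
  }
  out
}
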