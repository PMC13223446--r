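# Feedforward networks with paired lower/upper ("rough") weights.  Each
# rough neuron is a pair of conventional neurons sharing inputs: one fires
# from the lower-bound weights, one from the upper-bound weights, and the
# neuron emits the ordered interval (min, max) of the two sigmoid
# responses.  Between layers the interval is collapsed to its midpoint,
# which keeps hidden layers rough while giving the trainers a single
# differentiable path.  Weight intervals are initialised from the
# boundary-region fraction of a rough-set reduction: a fully consistent
# decision system (empty boundary) degenerates to a conventional network.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# row-wise softmax of an n x k matrix, vectorised
row_softmax <- function(M) {
  E <- exp(M - apply(M, 1, max))
  E / rowSums(E)
}

#' Pixel-level feature extraction
#'
#' Computes five deterministic per-pixel descriptors over an odd square
#' window: local mean, local variance, gradient magnitude (central
#' differences), local intensity range (a distance-to-boundary surrogate:
#' large near tissue interfaces, 0 deep inside homogeneous tissue), and
#' the 8-neighbour Laplacian response magnitude (the filter response).
#' Each descriptor is min-max normalised over the image.
#'
#' When a lesion mask (and optionally an artifact mask) is supplied, a
#' decision column is attached with classes `lesion`, `voxel-artifact`,
#' `background`, making the result directly usable as a
#' [decision_system()].
#'
#' @param img image matrix in `[0, 1]`.
#' @param window odd window width `>= 3` (default 5).
#' @param lesion_mask optional logical matrix marking lesion pixels.
#' @param artifact_mask optional logical matrix marking artifact pixels.
#' @param pixels optional integer vector of (column-major) pixel indices to
#'   sample; default all pixels.
#' @param levels optional number of equal-width quantisation levels applied
#'   to each feature column (for equivalence-class analysis upstream of the
#'   classical rough-set operators); `NULL` leaves features continuous.
#' @return data frame with feature columns `f_mean`, `f_var`, `f_grad`,
#'   `f_range`, `f_lap`, plus `pixel` (index) and, when masks are given,
#'   `decision`.
#' @export
features_from_image <- function(img, window = 5L, lesion_mask = NULL,
                                artifact_mask = NULL, pixels = NULL,
                                levels = NULL) {
  check_image(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window > min(dim(img))) stop("window larger than image")
  half <- (window - 1L) %/% 2L

  box <- rep(1 / window, window)
  mu <- conv_separable(img, box)
  mu2 <- conv_separable(img^2, box)
  f_var <- pmax(mu2 - mu^2, 0)

  gr <- (shift_matrix(img, -1L, 0L, NA) - shift_matrix(img, 1L, 0L, NA)) / 2
  gc <- (shift_matrix(img, 0L, -1L, NA) - shift_matrix(img, 0L, 1L, NA)) / 2
  gr[is.na(gr)] <- 0; gc[is.na(gc)] <- 0
  f_grad <- sqrt(gr^2 + gc^2)

  lo <- img; hi <- img
  for (dr in -half:half) {
    for (dc in -half:half) {
      if (dr == 0 && dc == 0) next
      s <- shift_matrix(img, dr, dc, NA)
      lo <- pmin(lo, s, na.rm = TRUE)
      hi <- pmax(hi, s, na.rm = TRUE)
    }
  }
  f_range <- hi - lo

  lap <- abs(conv2_full(img, matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)))

  feats <- data.frame(f_mean = as.vector(mu),
                      f_var = as.vector(f_var),
                      f_grad = as.vector(f_grad),
                      f_range = as.vector(f_range),
                      f_lap = as.vector(lap))
  feats[] <- lapply(feats, function(col) {
    rng <- range(col)
    if (rng[2] - rng[1] <= 0) col * 0 else (col - rng[1]) / (rng[2] - rng[1])
  })
  if (!is.null(levels)) {
    feats[] <- lapply(feats, function(col) {
      pmin(floor(col * levels), levels - 1) / levels
    })
  }
  feats$pixel <- seq_len(length(img))
  if (!is.null(lesion_mask)) {
    if (!identical(dim(lesion_mask), dim(img))) {
      stop("lesion_mask shape must match the image")
    }
    dec <- rep("background", length(img))
    if (!is.null(artifact_mask)) dec[as.vector(artifact_mask)] <- "voxel-artifact"
    dec[as.vector(lesion_mask)] <- "lesion"
    feats$decision <- dec
  }
  if (!is.null(pixels)) feats <- feats[pixels, , drop = FALSE]
  feats
}

#' Feature column names produced by [features_from_image()]
#' @return character vector of the five descriptor names.
#' @export
feature_names <- function() c("f_mean", "f_var", "f_grad", "f_range", "f_lap")

#' Initialise a rough network from a decision system and reduct
#'
#' Centre weights are drawn from a seeded uniform
#' `(-1/sqrt(fan_in), 1/sqrt(fan_in))` distribution.  The interval
#' half-width is `h * |BND(reduct)| / |U|`, the boundary-region fraction of
#' the reduct on the decision system: the more undecidable the reduct
#' leaves the data, the wider the weight intervals.  An empty boundary
#' (fully consistent system) gives `w_low == w_up` exactly.
#'
#' @param ds a [decision_system()] (typically pixel features with a
#'   decision column).
#' @param reduct non-empty character vector of selected attributes.
#' @param layer_sizes integer vector of layer widths, input first, output
#'   last.
#' @param seed integer seed for the centre draws.
#' @param h half-width scale (default 0.5).
#' @param classes output class labels (default the sorted unique decisions
#'   of `ds`); length must equal the output layer width.
#' @return an object of class `rough_network` with per-layer `w_low`,
#'   `w_up`, `b_low`, `b_up`.
#' @export
init_rough_weights <- function(ds, reduct, layer_sizes, seed = 1L, h = 0.5,
                               classes = NULL) {
  if (length(reduct) == 0) stop("reduct must be non-empty")
  check_attrs(ds, reduct)
  if (is.null(classes)) classes <- sort(unique(ds$decision))
  if (layer_sizes[length(layer_sizes)] != length(classes)) {
    stop("output layer width must equal the number of classes")
  }
  bnd <- positive_region(ds, reduct)$boundary
  halfw <- h * length(bnd) / length(ds$ids)
  set.seed(as.integer(seed))
  layers <- vector("list", length(layer_sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- layer_sizes[l]
    lim <- 1 / sqrt(fan_in)
    centre_w <- matrix(stats::runif(layer_sizes[l + 1L] * fan_in, -lim, lim),
                       layer_sizes[l + 1L], fan_in)
    centre_b <- stats::runif(layer_sizes[l + 1L], -lim, lim)
    layers[[l]] <- list(w_low = centre_w - halfw, w_up = centre_w + halfw,
                        b_low = centre_b - halfw, b_up = centre_b + halfw)
  }
  structure(list(layers = layers,
                 layer_sizes = as.integer(layer_sizes),
                 classes = classes,
                 half_width = halfw),
            class = "rough_network")
}

#' Rough neuron forward pass
#'
#' `net_low = w_low x + b_low`, `net_up = w_up x + b_up`;
#' `o_low = min(sigma(net_low), sigma(net_up))`,
#' `o_up  = max(sigma(net_low), sigma(net_up))`, so the output interval is
#' ordered by construction for arbitrary weights.
#'
#' @param x input vector.
#' @param w_low,w_up weight matrices (rows = neurons).
#' @param b_low,b_up bias vectors.
#' @return list with `o_low` and `o_up` vectors.
#' @export
rough_neuron_forward <- function(x, w_low, w_up, b_low, b_up) {
  if (ncol(w_low) != length(x) || !identical(dim(w_low), dim(w_up))) {
    stop("weight shapes do not conform to the input")
  }
  a_low <- sigmoid(as.vector(w_low %*% x + b_low))
  a_up <- sigmoid(as.vector(w_up %*% x + b_up))
  list(o_low = pmin(a_low, a_up), o_up = pmax(a_low, a_up))
}

# Batched forward over a feature matrix X (n x d): hidden layers propagate
# sigmoid interval midpoints; the OUTPUT layer emits the midpoint of its
# pre-activation interval (which is exactly the centre-weight response, the
# interval terms cancelling), so the class logits are unbounded and the
# softmax head behaves like a conventional classifier head.
network_forward_batch <- function(net, X) {
  A <- t(X)                                   # d x n
  nl_total <- length(net$layers)
  for (l in seq_len(nl_total)) {
    ly <- net$layers[[l]]
    if (l < nl_total) {
      nl <- sigmoid(ly$w_low %*% A + ly$b_low)
      nu <- sigmoid(ly$w_up %*% A + ly$b_up)
      A <- (pmin(nl, nu) + pmax(nl, nu)) / 2  # midpoint de-intervalisation
    } else {
      A <- ((ly$w_low + ly$w_up) / 2) %*% A + (ly$b_low + ly$b_up) / 2
    }
  }
  t(A)                                        # n x n_classes (logits)
}

#' Network forward pass: stage scores
#'
#' Propagates the input through every rough hidden layer, collapsing each
#' sigmoid output interval to its midpoint between layers; the output
#' layer emits the midpoint of its pre-activation interval (exactly the
#' centre-weight response, since the interval terms cancel under
#' averaging), and the logits are softmax-normalised into class scores.
#'
#' @param net a `rough_network`.
#' @param features numeric vector matching the input layer width.
#' @return named score vector (sums to 1, each score in (0, 1)).
#' @export
network_forward <- function(net, features) {
  if (length(features) != net$layer_sizes[1]) {
    stop("feature length must match the input layer")
  }
  out <- network_forward_batch(net, matrix(features, 1))
  stats::setNames(softmax(as.vector(out)), net$classes)
}

#' Predict a stage label
#'
#' Argmax of the class scores; exact ties break toward the earlier class
#' in the network's class ordering (for stages: the less severe one).
#'
#' @param net a `rough_network` whose classes are stage labels.
#' @param features input feature vector.
#' @return the predicted class label.
#' @export
predict_stage <- function(net, features) {
  s <- network_forward(net, features)
  net$classes[which.max(s)]
}

# flatten / unflatten midpoint parameters (used by the trainers)
net_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly) {
    c((ly$w_low + ly$w_up) / 2, (ly$b_low + ly$b_up) / 2)
  }))
}

net_get_halfwidths <- function(net) {
  unlist(lapply(net$layers, function(ly) {
    c((ly$w_up - ly$w_low) / 2, (ly$b_up - ly$b_low) / 2)
  }))
}

net_set_params <- function(net, centre, half = NULL) {
  if (is.null(half)) half <- net_get_halfwidths(net)
  half <- abs(half)
  off <- 0L
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    nw <- length(ly$w_low); nb <- length(ly$b_low)
    cw <- matrix(centre[off + seq_len(nw)], nrow(ly$w_low), ncol(ly$w_low))
    hw <- matrix(half[off + seq_len(nw)], nrow(ly$w_low), ncol(ly$w_low))
    off <- off + nw
    cb <- centre[off + seq_len(nb)]
    hb <- half[off + seq_len(nb)]
    off <- off + nb
    net$layers[[l]] <- list(w_low = cw - hw, w_up = cw + hw,
                            b_low = cb - hb, b_up = cb + hb)
  }
  net
}

# mean cross-entropy of the network on (X, y), y as class-index vector
net_cross_entropy <- function(net, X, y_idx, eps = 1e-12) {
  out <- network_forward_batch(net, X)
  P <- row_softmax(out)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), y_idx)], eps)))
}

#' Enhance an image by voxel-artifact suppression
#'
#' Scores every pixel with a 3-class (`lesion` / `voxel-artifact` /
#' `background`) rough network over the [features_from_image()]
#' descriptors and multiplies each intensity by
#' `1 - kappa * s_artifact`, where `s_artifact` is the softmax score of
#' the `voxel-artifact` class.  Pixels the network attributes to artifact
#' structure are darkened; lesion and tissue pixels pass through.  The
#' result is min-max renormalised to `[0, 1]`.
#'
#' @param net a `rough_network` with a `"voxel-artifact"` class trained or
#'   initialised on pixel features.
#' @param img image matrix in `[0, 1]`.
#' @param window feature window (must match the one the network was
#'   trained with).
#' @param kappa suppression strength in `[0, 1]` (default 0.8; 0 is
#'   identity).
#' @return enhanced image matrix in `[0, 1]`.
#' @export
enhance_image <- function(net, img, window = 5L, kappa = 0.8) {
  check_image(img)
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (kappa == 0) return(img)
  art <- match("voxel-artifact", net$classes)
  if (is.na(art)) stop("network has no 'voxel-artifact' class")
  feats <- features_from_image(img, window)
  X <- as.matrix(feats[, feature_names()])
  out <- network_forward_batch(net, X)
  P <- row_softmax(out)
  suppressed <- img * matrix(1 - kappa * P[, art], nrow(img), ncol(img))
  minmax_normalize(clip01(suppressed))
}
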