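test_that("pixel features match brute-force window statistics", {
  const <- matrix(0.4, 12, 12)
  f <- features_from_image(const, 5)
  expect_true(all(f$f_var == 0))
  expect_true(all(f$f_grad == 0))
  expect_length(feature_names(), 5)
  expect_true(all(feature_names() %in% names(f)))

  expect_error(features_from_image(const, 4), "odd")
  expect_error(features_from_image(const, 15), "larger than image")

  # interior local mean equals brute-force window averaging (un-normalised
  # comparison via a second constant-free image)
  set.seed(6)
  img <- matrix(runif(144), 12, 12)
  w <- 3; half <- 1
  mu <- matrix(NA_real_, 12, 12)
  for (i in 2:11) {
    for (j in 2:11) {
      mu[i, j] <- mean(img[(i - half):(i + half), (j - half):(j + half)])
    }
  }
  interior <- !is.na(mu)
  mu_norm <- (mu - min(roughmri:::conv_separable(img, rep(1 / 3, 3)))) /
    diff(range(roughmri:::conv_separable(img, rep(1 / 3, 3))))
  f3 <- features_from_image(img, 3)
  got <- matrix(f3$f_mean, 12, 12)
  expect_equal(got[interior], mu_norm[interior], tolerance = 1e-12)
})

test_that("feature decisions follow the masks", {
  img <- matrix(0.5, 8, 8)
  les <- matrix(FALSE, 8, 8); les[2, 2] <- TRUE
  art <- matrix(FALSE, 8, 8); art[5, 5] <- TRUE
  f <- features_from_image(img, 3, lesion_mask = les, artifact_mask = art)
  expect_equal(sum(f$decision == "lesion"), 1)
  expect_equal(sum(f$decision == "voxel-artifact"), 1)
  expect_equal(sum(f$decision == "background"), 62)
})

test_that("interval initialisation scales with the boundary fraction", {
  ds <- worked_example_ds()
  net <- init_rough_weights(ds, c("a", "b"), c(2, 4, 2), seed = 3, h = 0.5,
                            classes = c("0", "1"))
  # boundary of {a, b} on the worked example is {u2, u3}: fraction 2/8
  expect_equal(net$half_width, 0.5 * 2 / 8)
  for (ly in net$layers) {
    expect_true(all(ly$w_low <= ly$w_up))
    expect_true(all(ly$b_low <= ly$b_up))
    expect_equal(ly$w_up - ly$w_low,
                 matrix(2 * net$half_width, nrow(ly$w_up), ncol(ly$w_up)))
  }
  # same seed, same network
  expect_identical(net, init_rough_weights(ds, c("a", "b"), c(2, 4, 2),
                                           seed = 3, h = 0.5,
                                           classes = c("0", "1")))
  # consistent system (empty boundary): degenerate intervals
  cons <- decision_system(data.frame(x = 1:4), c(0, 0, 1, 1))
  net0 <- init_rough_weights(cons, "x", c(1, 3, 2), seed = 1,
                             classes = c("0", "1"))
  expect_equal(net0$half_width, 0)
  expect_identical(net0$layers[[1]]$w_low, net0$layers[[1]]$w_up)
  expect_error(init_rough_weights(ds, character(0), c(2, 2)), "non-empty")
})

test_that("rough neurons emit ordered intervals", {
  # hand evaluation: x = (1, -1), w_low = (.5, .5), w_up = (1, 1), b = 0
  out <- rough_neuron_forward(c(1, -1), matrix(c(0.5, 0.5), 1),
                              matrix(c(1, 1), 1), 0, 0)
  expect_equal(out$o_low, 0.5)
  expect_equal(out$o_up, 0.5)
  # degenerate interval
  w <- matrix(c(0.3, -0.2), 1)
  out2 <- rough_neuron_forward(c(0.4, 0.9), w, w, 0.1, 0.1)
  expect_equal(out2$o_low, out2$o_up)
  expect_error(rough_neuron_forward(c(1, 2, 3), w, w, 0, 0), "conform")
  # ordered for arbitrary weights: 1000 seeded trials
  set.seed(99)
  for (k in 1:1000) {
    d <- sample(2:5, 1)
    m <- sample(1:4, 1)
    wl <- matrix(rnorm(m * d), m, d)
    wu <- matrix(rnorm(m * d), m, d)
    o <- rough_neuron_forward(rnorm(d), wl, wu, rnorm(m), rnorm(m))
    expect_true(all(o$o_low <= o$o_up))
  }
})

test_that("network scores are a proper distribution and match hand computation", {
  ds <- worked_example_ds()
  net <- init_rough_weights(ds, c("a", "b"), c(2, 3, 3), seed = 5,
                            classes = c("x", "y", "z"))
  s <- network_forward(net, c(0.2, 0.9))
  expect_equal(sum(s), 1)
  expect_true(all(s > 0 & s < 1))
  expect_error(network_forward(net, c(1, 2, 3)), "match the input")

  # two-layer toy net with hand-set weights, computed by hand
  toy <- net
  toy$layers <- list(
    list(w_low = matrix(c(1, 0, 1, 0, 1, 1), 3, 2), b_low = c(0, 0, 0),
         w_up = matrix(c(1, 0, 1, 0, 1, 1), 3, 2), b_up = c(0, 0, 0)),
    list(w_low = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3),
         b_low = c(0, 0, 0),
         w_up = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3),
         b_up = c(0, 0, 0)))
  toy$layer_sizes <- c(2L, 3L, 3L)
  x <- c(1, -1)
  hidden <- 1 / (1 + exp(-c(1 * 1 + (-1) * 0, 0 - 1, 1 - 1)))   # sigmoid(Wx)
  logits <- hidden                                              # identity head
  expect_equal(as.vector(network_forward(toy, x)),
               exp(logits) / sum(exp(logits)), tolerance = 1e-12)
})

test_that("degenerate intervals reproduce a conventional forward pass", {
  set.seed(12)
  ds <- decision_system(data.frame(x = 1:6, y = 6:1),
                        c(0, 0, 1, 1, 2, 2))
  net <- init_rough_weights(ds, c("x", "y"), c(2, 4, 3), seed = 2,
                            classes = c("0", "1", "2"))
  # force degenerate intervals at the current centres
  centre <- roughmri:::net_get_params(net)
  degen <- roughmri:::net_set_params(net, centre, half = 0 * centre)
  # conventional network evaluated by hand from the same centres
  conv_forward <- function(x) {
    a <- x
    nl <- length(degen$layers)
    for (l in seq_len(nl)) {
      ly <- degen$layers[[l]]
      z <- as.vector(ly$w_low %*% a + ly$b_low)
      a <- if (l < nl) 1 / (1 + exp(-z)) else z
    }
    exp(a - max(a)) / sum(exp(a - max(a)))
  }
  for (k in 1:20) {
    x <- runif(2)
    expect_equal(as.vector(network_forward(degen, x)), conv_forward(x),
                 tolerance = 1e-12)
  }
})

test_that("stage prediction breaks ties toward the less severe stage", {
  ds <- decision_system(data.frame(x = 1:6), rep(stage_levels(), 2))
  net <- init_rough_weights(ds, "x", c(1, 3), seed = 1,
                            classes = stage_levels())
  # zero out everything: all logits equal, scores tie three ways
  net0 <- roughmri:::net_set_params(net,
                                    0 * roughmri:::net_get_params(net),
                                    0 * roughmri:::net_get_halfwidths(net))
  expect_equal(predict_stage(net0, 0.5), "mild")
  s <- network_forward(net0, 0.5)
  expect_equal(as.vector(s), rep(1 / 3, 3))
})

test_that("forward pass is deterministic to machine precision", {
  ds <- worked_example_ds()
  net <- init_rough_weights(ds, c("a", "b"), c(2, 16, 3), seed = 8,
                            classes = c("x", "y", "z"))
  x <- c(0.3, 0.7)
  a <- replicate(5, network_forward(net, x))
  expect_true(all(abs(a - a[, 1]) < 1e-12))
})

test_that("artifact suppression is bounded, identity at kappa 0, and helps MCC", {
  set.seed(33)
  spec <- phantom_spec(height = 96L, width = 96L,
                       lesion_count_range = c(4L, 4L),
                       lesion_radius_range = c(2, 4), seed = 17)
  s <- generate_phantom(spec)
  gain <- make_emphasis_gain(dim(s$image))
  ahf <- anti_homomorphic_filter(s$image, gain)
  feats <- features_from_image(ahf, 5, lesion_mask = s$lesion_mask,
                               artifact_mask = s$artifact_mask)
  set.seed(1)
  keep <- unlist(lapply(split(seq_len(nrow(feats)), feats$decision),
                        function(ix) sample(ix, min(400, length(ix)))))
  tr <- feats[keep, ]
  lv <- 8
  ds <- decision_system(
    as.data.frame(lapply(tr[, feature_names()],
                         function(col) pmin(floor(col * lv), lv - 1))),
    tr$decision)
  net <- init_rough_weights(ds, feature_names(), c(5, 3), seed = 1,
                            classes = c("background", "lesion",
                                        "voxel-artifact"))
  fit <- train_stage_classifier(net, list(X = as.matrix(tr[, feature_names()]),
                                          y = tr$decision),
                                "rmlm", max_iter = 150)

  expect_identical(enhance_image(fit$net, ahf, 5, kappa = 0), ahf)
  enh <- enhance_image(fit$net, ahf, 5, kappa = 0.8)
  expect_true(all(enh >= 0 & enh <= 1))
  mcc_of <- function(img) {
    metrics_from_counts(confusion_counts(roughmri:::lesion_candidates(img),
                                         s$lesion_mask))$mcc
  }
  expect_gte(mcc_of(enh), mcc_of(ahf))
})
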