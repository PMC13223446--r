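# End-to-end orchestration: phantom generation -> anti-homomorphic
# enhancement -> pixel features -> rough-set reduction -> interval weight
# initialisation -> metaheuristic tuning of the pixel suppressor ->
# artifact suppression -> stage-classifier training -> metrics.  Every
# stage is seeded from the run seed, logs its parameters, and aborts with
# its own name on failure.

#' Default pipeline configuration
#'
#' @param n_images number of phantoms to generate.
#' @param seed master run seed; all stage seeds derive from it.
#' @param train_fraction fraction of images used for training (default
#'   2/3).
#' @param filter list of gain parameters (`gamma_low`, `gamma_high`,
#'   `c_sharp`, `d0`, `eps`).
#' @param reduction `method` (`"lrsm"` or `"nbdrs"`) plus `levels`
#'   (feature quantisation for the classical operators), `delta`,
#'   `epsilon` for the neighborhood variant, and `n_pixels` sampled per
#'   training image.
#' @param optimizer `kind` (`"pso"`, `"poa"`, `"ho"`), `n_agents`,
#'   `n_iter`.
#' @param trainer `kind` (`"cg"`, `"lm"`, `"rmlm"`), `max_iter`.
#' @param enhance `kappa` suppression strength, `window` feature window,
#'   `hidden` hidden-layer width.
#' @param phantom overrides passed to [phantom_spec()] (a list).
#' @return a `pipeline_config` list, schema-checked by
#'   [validate_pipeline_config()].
#' @export
pipeline_config <- function(n_images = 60L, seed = 1L,
                            train_fraction = 2 / 3,
                            filter = list(),
                            reduction = list(),
                            optimizer = list(),
                            trainer = list(),
                            enhance = list(),
                            phantom = list()) {
  config <- list(
    n_images = as.integer(n_images),
    seed = as.integer(seed),
    train_fraction = train_fraction,
    filter = utils::modifyList(
      list(gamma_low = 0.5, gamma_high = 2.0, c_sharp = 1, d0 = 0.1,
           eps = 1e-6), filter),
    reduction = utils::modifyList(
      list(method = "lrsm", levels = 8L, delta = 0.15, epsilon = 0,
           n_pixels = 400L), reduction),
    optimizer = utils::modifyList(
      list(kind = "pso", n_agents = 20L, n_iter = 60L), optimizer),
    trainer = utils::modifyList(
      list(kind = "rmlm", max_iter = 150L), trainer),
    enhance = utils::modifyList(
      list(kappa = 0.8, window = 5L, hidden = 16L), enhance),
    phantom = phantom
  )
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' Schema-checks the configuration before any stage runs.
#'
#' @param config a `pipeline_config` (or plain list with the same fields).
#' @return the config, invisibly; errors name the offending field.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$n_images) || config$n_images < 1) {
    stop("config error: n_images must be at least 1")
  }
  if (config$train_fraction <= 0 || config$train_fraction >= 1) {
    stop("config error: train_fraction must lie in (0, 1)")
  }
  if (!config$reduction$method %in% c("lrsm", "nbdrs")) {
    stop("config error: reduction$method must be 'lrsm' or 'nbdrs'")
  }
  if (!config$optimizer$kind %in% c("pso", "poa", "ho")) {
    stop("config error: optimizer$kind must be 'pso', 'poa', or 'ho'")
  }
  if (!config$trainer$kind %in% c("cg", "lm", "rmlm")) {
    stop("config error: trainer$kind must be 'cg', 'lm', or 'rmlm'")
  }
  if (config$enhance$kappa < 0 || config$enhance$kappa > 1) {
    stop("config error: enhance$kappa must lie in [0, 1]")
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with (a subset of) the [pipeline_config()]
#'   fields.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Per-image aggregate descriptors of an enhanced slice, used by the stage
# classifier.  The pixel suppressor's class-score maps provide the lesion
# and artifact burden estimates (stage is by construction a function of
# lesion burden); global intensity and gradient summaries round out the
# vector.
image_stage_features <- function(img, pixel_net, window) {
  feats <- features_from_image(img, window)
  P <- row_softmax(network_forward_batch(pixel_net,
                                         as.matrix(feats[, feature_names()])))
  colnames(P) <- pixel_net$classes
  gr <- (shift_matrix(img, -1L, 0L, NA) - shift_matrix(img, 1L, 0L, NA)) / 2
  gr[is.na(gr)] <- 0
  c(les_frac = mean(P[, "lesion"] > 0.5),
    les_score = mean(P[, "lesion"]),
    art_frac = mean(P[, "voxel-artifact"] > 0.5),
    mean_int = mean(img),
    q99 = as.numeric(stats::quantile(img, 0.99)),
    grad_energy = mean(gr^2))
}

#' Run the full enhancement / classification pipeline
#'
#' Stages, in order: phantom generation; anti-homomorphic filtering;
#' pixel feature extraction on the training images; attribute reduction
#' (classical local-redundancy or neighborhood entropy); interval weight
#' initialisation from the reduct's boundary region; metaheuristic tuning
#' of the 3-class pixel suppressor; artifact suppression of every slice;
#' stage-classifier training on per-image aggregates of the enhanced
#' slices; pixel-level and image-level evaluation on the held-out split.
#'
#' @param config a [pipeline_config()].
#' @return report list with `config`, `reduct`, `pixel_metrics` (full
#'   pipeline), `ahf_metrics` (filter-only branch), `stage` (stage
#'   report on the test split), `train_history`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  seed <- config$seed

  samples <- stage_try("phantom", {
    lapply(seq_len(config$n_images), function(i) {
      spec <- do.call(phantom_spec,
                      c(list(seed = seed + i), config$phantom))
      generate_phantom(spec)
    })
  })

  filtered <- stage_try("filter", {
    fp <- config$filter
    gain <- make_emphasis_gain(dim(samples[[1]]$image), fp$gamma_low,
                               fp$gamma_high, fp$c_sharp, fp$d0)
    lapply(samples, function(s) {
      anti_homomorphic_filter(s$image, gain, eps = fp$eps)
    })
  })

  n_train <- max(1L, round(config$train_fraction * config$n_images))
  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_along(samples), train_idx)
  if (length(test_idx) == 0) stop("pipeline stage 'split' failed: no test images")

  pixel_train <- stage_try("features", {
    set.seed(seed)
    # class-weighted pixel sample: background kept dominant (half the
    # draw) so the classifier is not trained far from the test-time class
    # prior, but lesion and artifact stay well represented
    want <- c(background = ceiling(config$reduction$n_pixels / 2),
              lesion = ceiling(config$reduction$n_pixels / 4),
              `voxel-artifact` = ceiling(config$reduction$n_pixels / 4))
    rows <- lapply(train_idx[seq_len(min(8L, n_train))], function(i) {
      s <- samples[[i]]
      f <- features_from_image(filtered[[i]], config$enhance$window,
                               lesion_mask = s$lesion_mask,
                               artifact_mask = s$artifact_mask)
      idx <- unlist(lapply(names(want), function(cl) {
        ix <- which(f$decision == cl)
        if (length(ix) <= want[[cl]]) ix else sample(ix, want[[cl]])
      }))
      f[sort(idx), , drop = FALSE]
    })
    do.call(rbind, rows)
  })

  reduct <- stage_try("reduce", {
    feat_cols <- pixel_train[, feature_names()]
    if (config$reduction$method == "lrsm") {
      lv <- config$reduction$levels
      binned <- as.data.frame(lapply(feat_cols, function(col) {
        pmin(floor(col * lv), lv - 1)
      }))
      ds <- decision_system(binned, pixel_train$decision)
      lrsm_reduce(ds)
    } else {
      ds <- decision_system(feat_cols, pixel_train$decision)
      ns <- neighborhood_system(ds, delta = config$reduction$delta)
      red <- nbd_rs_reduce(ns, config$reduction$epsilon)
      if (length(red) == 0) red <- feature_names()[1]
      red
    }
  })

  pixel_net <- stage_try("init_weights", {
    lv <- config$reduction$levels
    binned <- as.data.frame(lapply(pixel_train[, feature_names()],
                                   function(col) pmin(floor(col * lv), lv - 1)))
    ds <- decision_system(binned, pixel_train$decision)
    # the suppressor is a single rough layer (softmax regression over the
    # pixel descriptors): small enough for the metaheuristics to tune
    # within their iteration budget
    init_rough_weights(ds, reduct,
                       layer_sizes = c(length(feature_names()), 3L),
                       seed = seed,
                       classes = c("background", "lesion", "voxel-artifact"))
  })

  pixel_net <- stage_try("tune", {
    tune_rough_weights(
      pixel_net,
      list(X = as.matrix(pixel_train[, feature_names()]),
           y = pixel_train$decision),
      optimizer_kind = config$optimizer$kind,
      config = optimizer_config(n_agents = config$optimizer$n_agents,
                                n_iter = config$optimizer$n_iter,
                                bounds = rbind(0, 1), seed = seed),
      bound_width = 4)
  })

  enhanced <- stage_try("enhance", {
    lapply(filtered, function(img) {
      enhance_image(pixel_net, img, config$enhance$window,
                    config$enhance$kappa)
    })
  })

  pixel_eval <- stage_try("pixel_eval", {
    eval_masks <- function(imgs) {
      counts <- list(TP = 0, TN = 0, FP = 0, FN = 0)
      for (i in test_idx) {
        pred <- lesion_candidates(imgs[[i]])
        cc <- confusion_counts(pred, samples[[i]]$lesion_mask)
        counts$TP <- counts$TP + cc$TP; counts$TN <- counts$TN + cc$TN
        counts$FP <- counts$FP + cc$FP; counts$FN <- counts$FN + cc$FN
      }
      metrics_from_counts(counts)
    }
    list(pipeline = eval_masks(enhanced), ahf_only = eval_masks(filtered))
  })

  stage_fit <- stage_try("train", {
    Xs <- t(vapply(enhanced, function(img) {
      image_stage_features(img, pixel_net, config$enhance$window)
    }, numeric(6)))
    ys <- vapply(samples, function(s) s$stage, "")
    Xs <- apply(Xs, 2, function(col) {
      rng <- range(col[train_idx])
      if (rng[2] - rng[1] <= 0) col * 0
      else pmin(pmax((col - rng[1]) / (rng[2] - rng[1]), 0), 1)
    })
    stage_ds <- decision_system(
      as.data.frame(lapply(as.data.frame(Xs[train_idx, , drop = FALSE]),
                           function(col) pmin(floor(col * 8), 7))),
      ys[train_idx])
    stage_net <- init_rough_weights(
      stage_ds, colnames(Xs), layer_sizes = c(6L, config$enhance$hidden, 3L),
      seed = seed, classes = stage_levels())
    fit <- train_stage_classifier(
      stage_net,
      list(X = Xs[train_idx, , drop = FALSE], y = ys[train_idx]),
      trainer_kind = config$trainer$kind,
      max_iter = config$trainer$max_iter)
    preds <- vapply(test_idx, function(i) {
      predict_stage(fit$net, Xs[i, ])
    }, "")
    list(net = fit$net, history = fit$history,
         report = stage_report(preds, ys[test_idx]))
  })

  list(
    config = config,
    reduct = reduct,
    pixel_metrics = pixel_eval$pipeline,
    ahf_metrics = pixel_eval$ahf_only,
    stage = stage_fit$report,
    train_history = stage_fit$history,
    provenance = list(
      package_version = as.character(utils::packageVersion("roughmri")),
      config_hash = digest_config(config),
      n_train = n_train, n_test = length(test_idx)
    )
  )
}

# small deterministic config fingerprint (no external digest dependency)
digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Write a pipeline report as JSON
#' @param report list returned by [run_pipeline()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
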