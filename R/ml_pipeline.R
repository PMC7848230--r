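#' Random-forest hyperparameters
#'
#' Defaults follow the study design: shallow trees (depth 3), 200 trees, 50%
#' of features tried at each split, and class weights inversely proportional
#' to training-class frequency.
#'
#' @param depth maximal tree depth.
#' @param trees number of trees.
#' @param mtry_frac fraction of features tried at each split.
#' @param balanced use balanced class weights.
#' @return a named list of class `"rf_params"`.
#' @export
rf_params <- function(depth = 3, trees = 200, mtry_frac = 0.5,
                      balanced = TRUE) {
  stopifnot(depth >= 1, trees >= 1, mtry_frac > 0, mtry_frac <= 1)
  structure(list(depth = depth, trees = trees, mtry_frac = mtry_frac,
                 balanced = balanced), class = "rf_params")
}

#' Balanced class weights
#'
#' Computes `n / (k * n_c)` per class: weights inversely proportional to the
#' class frequencies in the training labels.
#'
#' @param y factor or character vector of training labels.
#' @return named numeric vector of per-class weights.
#' @export
balanced_class_weights <- function(y) {
  tab <- table(y)
  n <- length(y)
  stats::setNames(as.numeric(n / (length(tab) * tab)), names(tab))
}

# Deterministic seed derivation: any single iteration / sub-iteration can be
# re-run from the master seed and its index path alone.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  val <- (seed * 48271 + sum(idx * 7919^seq_along(idx))) %% 2147483629
  as.integer(val + 1)
}

fit_rf <- function(x, y, params, seed, positive) {
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("training fold contains a single class: ", levels(y))
  cw <- if (params$balanced) balanced_class_weights(y) else
    stats::setNames(rep(1, nlevels(y)), levels(y))
  ranger::ranger(x = x, y = y,
                 num.trees = params$trees,
                 mtry = max(1L, floor(params$mtry_frac * ncol(x))),
                 max.depth = params$depth,
                 probability = TRUE,
                 class.weights = as.numeric(cw[levels(y)]),
                 importance = "impurity",
                 seed = seed, num.threads = 1)
}

predict_prob <- function(fit, x, positive) {
  p <- stats::predict(fit, data = x, num.threads = 1)$predictions
  p[, positive]
}

# Zero-fill a feature matrix to a fixed column set (e.g. a test cohort that
# lacks some training features).
align_features <- function(m, features) {
  out <- matrix(0, nrow(m), length(features),
                dimnames = list(rownames(m), features))
  common <- intersect(colnames(m), features)
  out[, common] <- m[, common, drop = FALSE]
  out
}

#' Enumerate classifier configurations
#'
#' Crosses the dataset-division strategies with predictor sets and disease
#' contrasts. With `n >= 2` datasets the strategies contribute `n` Single
#' variants, `n` leave-one-dataset-out (L1O) variants and one Mixed variant
#' (`2n + 1` in total, 7 for three cohorts); a lone dataset supports only its
#' Single variant. Three cohorts, two predictor sets and two contrasts yield
#' the full set of 28 configurations.
#'
#' @param dataset_ids character vector of cohort labels.
#' @param predictor_sets subset of `c("taxonomy", "phenotype")`.
#' @param contrasts disease classes contrasted with `"HC"`.
#' @param rf an [rf_params()] object.
#' @param n_iterations_single cross-validation iterations for Single/Mixed.
#' @param n_iterations_l1o iterations for L1O variants.
#' @param n_sub feature-extraction sub-iterations.
#' @param top_k number of features kept by extraction.
#' @param seed master seed.
#' @return list of `"classifier_config"` objects.
#' @export
enumerate_configs <- function(dataset_ids,
                              predictor_sets = c("taxonomy", "phenotype"),
                              contrasts = c("CD", "UC"),
                              rf = rf_params(),
                              n_iterations_single = 10, n_iterations_l1o = 3,
                              n_sub = 10, top_k = 20, seed = 1) {
  stopifnot(length(dataset_ids) >= 1)
  variants <- data.frame(strategy = "Single", variant = dataset_ids)
  if (length(dataset_ids) >= 2) {
    variants <- rbind(variants,
                      data.frame(strategy = "L1O", variant = dataset_ids),
                      data.frame(strategy = "Mixed", variant = "all"))
  }
  configs <- list()
  for (ps in predictor_sets) for (ct in contrasts)
    for (v in seq_len(nrow(variants))) {
      strat <- variants$strategy[v]
      configs[[length(configs) + 1L]] <- classifier_config(
        strategy = strat, variant = variants$variant[v],
        predictor_set = ps, contrast = ct, rf = rf,
        n_iterations = if (strat == "L1O") n_iterations_l1o
                       else n_iterations_single,
        n_sub = n_sub, top_k = top_k,
        seed = derive_seed(seed, length(configs) + 1L))
    }
  configs
}

#' Classifier configuration
#'
#' @param strategy one of `"Single"`, `"Mixed"`, `"L1O"`.
#' @param variant dataset id for Single, held-out dataset for L1O, `"all"`
#'   for Mixed.
#' @param predictor_set `"taxonomy"` or `"phenotype"`.
#' @param contrast disease class contrasted with `"HC"`.
#' @inheritParams enumerate_configs
#' @param n_iterations cross-validation iterations.
#' @return a list of class `"classifier_config"`.
#' @export
classifier_config <- function(strategy, variant, predictor_set, contrast,
                              rf = rf_params(), n_iterations = 10,
                              n_sub = 10, top_k = 20, seed = 1) {
  stopifnot(strategy %in% c("Single", "Mixed", "L1O"),
            predictor_set %in% c("taxonomy", "phenotype"),
            contrast %in% c("CD", "UC"))
  structure(list(strategy = strategy, variant = variant,
                 predictor_set = predictor_set, contrast = contrast,
                 rf = rf, n_iterations = n_iterations, n_sub = n_sub,
                 top_k = top_k, seed = seed),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat(sprintf("%s:%s | %s | %s-vs-HC | %d iterations\n", x$strategy,
              x$variant, x$predictor_set, x$contrast, x$n_iterations))
  invisible(x)
}

#' Equalize group sizes across datasets
#'
#' For each clinical status, the subsampling target is the minimum group size
#' across the participating datasets; that many samples are then drawn
#' uniformly without replacement from every dataset's group, so each cohort
#' contributes equally to the pooled set.
#'
#' @param labels_by_dataset named list; each element a named character vector
#'   of sample id -> clinical status for one dataset.
#' @param statuses statuses to equalize (default: all statuses present in
#'   every dataset).
#' @param seed integer seed for the uniform draws.
#' @return list with `targets` (named vector of per-status target counts) and
#'   `ids` (per dataset, the sampled ids).
#' @export
subsample_equalize <- function(labels_by_dataset, statuses = NULL, seed = 1) {
  if (is.null(statuses))
    statuses <- Reduce(intersect, lapply(labels_by_dataset,
                                         function(l) unique(l)))
  statuses <- sort(statuses)
  targets <- vapply(statuses, function(s) {
    min(vapply(labels_by_dataset, function(l) sum(l == s), numeric(1)))
  }, numeric(1))
  if (any(targets < 1))
    stop("status absent from some dataset: ",
         paste(statuses[targets < 1], collapse = ", "))
  rng <- local_seed(seed)
  ids <- lapply(labels_by_dataset, function(l) {
    unlist(lapply(statuses, function(s) {
      pool <- names(l)[l == s]
      sample(pool, targets[[s]])
    }), use.names = FALSE)
  })
  list(targets = targets, ids = ids)
}

# All stochastic steps reseed explicitly from derived seeds, so every
# iteration is re-runnable in isolation.
local_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

#' Filter taxonomic features on training data
#'
#' Retains genus-level features that, in every training dataset separately,
#' have nonzero abundance in at least `min_samples` samples and a maximum
#' abundance of at least `min_max_abund`.
#'
#' @param tables list of samples x features abundance matrices, one per
#'   training dataset.
#' @param min_samples minimal number of samples with nonzero abundance
#'   (default 5: features nonzero in fewer than 5 samples are dropped).
#' @param min_max_abund minimal maximum abundance (default 0.01: features
#'   never reaching 1% are dropped).
#' @return character vector of retained feature names.
#' @export
filter_taxonomic_features <- function(tables, min_samples = 5,
                                      min_max_abund = 0.01) {
  features <- Reduce(intersect, lapply(tables, colnames))
  keep <- vapply(features, function(f) {
    all(vapply(tables, function(tb) {
      v <- tb[, f]
      sum(v > 0) >= min_samples && max(v) >= min_max_abund
    }, logical(1)))
  }, logical(1))
  features[keep]
}

#' Filter phenotype features on training data
#'
#' Retains phenotypes that, in every training dataset separately, have a mean
#' CPI inside `cpi_range`, a CPI above `carrier_cpi` in at least
#' `min_carrier_samples` samples, and a mean PAD of at least `min_mean_pad`.
#' The PAD rule removes phenotypes whose CPI is contributed by a
#' phylogenetically narrow group of carriers, for which the index would track
#' the abundance of a single clade rather than a community-wide function.
#'
#' @param cpi_tables list of samples x phenotypes CPI matrices (training rows
#'   per dataset).
#' @param pad_tables matching list of PAD matrices.
#' @param cpi_range closed interval for the mean CPI (default `[0.1, 0.9]`).
#' @param carrier_cpi CPI threshold for the prevalence rule (default 0.05).
#' @param min_carrier_samples minimal number of samples above `carrier_cpi`
#'   (default 5).
#' @param min_mean_pad minimal mean PAD (default 3.5; phenotypes below are
#'   dropped).
#' @return character vector of retained phenotype names.
#' @export
filter_phenotype_features <- function(cpi_tables, pad_tables,
                                      cpi_range = c(0.1, 0.9),
                                      carrier_cpi = 0.05,
                                      min_carrier_samples = 5,
                                      min_mean_pad = 3.5) {
  stopifnot(length(cpi_tables) == length(pad_tables))
  features <- Reduce(intersect, lapply(cpi_tables, colnames))
  keep <- vapply(features, function(f) {
    all(vapply(seq_along(cpi_tables), function(d) {
      cpi <- cpi_tables[[d]][, f]
      pad <- pad_tables[[d]][, f]
      m <- mean(cpi)
      m >= cpi_range[1] && m <= cpi_range[2] &&
        sum(cpi > carrier_cpi) >= min_carrier_samples &&
        mean(pad) >= min_mean_pad
    }, logical(1)))
  }, logical(1))
  features[keep]
}

#' Extract top features by mean random-forest importance
#'
#' Runs `n_sub` seeded random-forest fits on the training data, averages the
#' per-forest Gini importances (each normalized to sum 1), and returns the
#' `top_k` features with the highest mean importance; ties break
#' lexicographically.
#'
#' @param x training samples x features matrix (already filtered).
#' @param y training labels.
#' @param params an [rf_params()] object.
#' @param n_sub number of sub-iterations.
#' @param top_k number of features to keep (all features if fewer).
#' @param seed seed from which sub-iteration seeds are derived.
#' @return character vector of selected feature names.
#' @export
extract_top_features <- function(x, y, params = rf_params(), n_sub = 10,
                                 top_k = 20, seed = 1) {
  imp <- matrix(0, n_sub, ncol(x), dimnames = list(NULL, colnames(x)))
  for (s in seq_len(n_sub)) {
    fit <- fit_rf(x, y, params, seed = derive_seed(seed, s))
    v <- fit$variable.importance
    if (sum(v) > 0) v <- v / sum(v)
    imp[s, names(v)] <- v
  }
  mean_imp <- colMeans(imp)
  ord <- order(-mean_imp, colnames(x))
  colnames(x)[ord][seq_len(min(top_k, ncol(x)))]
}

# Stratified train/test split: per class, round(frac * n) training samples,
# clamped so both sides keep at least one sample of each class.
split_stratified <- function(y, frac = 2 / 3, seed = 1) {
  local_seed(seed)
  train <- unlist(lapply(split(seq_along(y), y), function(idx) {
    n_tr <- min(max(round(frac * length(idx)), 1L), length(idx) - 1L)
    sample(idx, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

#' Train and evaluate one classifier configuration
#'
#' Runs the configured number of cross-validation iterations. Each iteration
#' builds its train/test split according to the strategy (Single: stratified
#' two-thirds/one-third within one cohort; Mixed: per-cohort equalized
#' subsample redrawn each iteration, then a stratified two-thirds split; L1O:
#' the two training cohorts subsampled to their per-status minimum, the
#' held-out cohort as test set), filters features on the training rows of
#' each cohort separately, extracts the top features by mean importance, fits
#' the final random forest and evaluates ROC-AUC plus sensitivity and
#' specificity (disease = positive class, probability threshold 0.5).
#'
#' @param config a [classifier_config()].
#' @param datasets named list; each element a list with `taxonomy` (samples x
#'   genus features), `phenotype` (samples x phenotypes CPI), `pad` (matching
#'   PAD matrix) and `labels` (named status vector).
#' @param threshold class-probability operating point for
#'   sensitivity/specificity (default 0.5).
#' @return list of per-iteration results (`auc`, `sensitivity`,
#'   `specificity`, `features`, `importances` over the feature universe with
#'   0 for non-extracted features), with the feature universe as an
#'   attribute.
#' @export
train_and_evaluate <- function(config, datasets, threshold = 0.5) {
  positive <- config$contrast
  classes <- c("HC", positive)
  ps <- config$predictor_set
  feat_of <- function(d) datasets[[d]][[ps]]
  lab_of <- function(d) datasets[[d]]$labels

  participating <- switch(config$strategy,
    Single = config$variant,
    Mixed = names(datasets),
    L1O = names(datasets))
  universe <- sort(unique(unlist(lapply(participating,
                                        function(d) colnames(feat_of(d))))))

  results <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    seed_i <- derive_seed(config$seed, i)

    # --- assemble training/test sample ids per dataset ------------------
    if (config$strategy == "Single") {
      d <- config$variant
      lab <- lab_of(d)
      sel <- names(lab)[lab %in% classes]
      sp <- split_stratified(lab[sel], seed = seed_i)
      train_ids <- stats::setNames(list(sel[sp$train]), d)
      test_ids <- stats::setNames(list(sel[sp$test]), d)
    } else if (config$strategy == "Mixed") {
      labs <- lapply(datasets, function(x) {
        l <- x$labels
        l[l %in% classes]
      })
      sub <- subsample_equalize(labs, statuses = classes,
                                seed = derive_seed(seed_i, 1))
      pooled <- unlist(lapply(names(sub$ids), function(d) {
        stats::setNames(lab_of(d)[sub$ids[[d]]], sub$ids[[d]])
      }))
      sp <- split_stratified(pooled, seed = derive_seed(seed_i, 2))
      train_pool <- names(pooled)[sp$train]
      test_pool <- names(pooled)[sp$test]
      train_ids <- lapply(names(datasets), function(d)
        intersect(sub$ids[[d]], train_pool))
      names(train_ids) <- names(datasets)
      test_ids <- stats::setNames(list(test_pool), "pooled")
    } else { # L1O
      held_out <- config$variant
      train_ds <- setdiff(names(datasets), held_out)
      labs <- lapply(datasets[train_ds], function(x) {
        l <- x$labels
        l[l %in% classes]
      })
      sub <- subsample_equalize(labs, statuses = classes,
                                seed = derive_seed(seed_i, 1))
      train_ids <- sub$ids
      lab <- lab_of(held_out)
      test_ids <- stats::setNames(list(names(lab)[lab %in% classes]),
                                  held_out)
    }
    train_ids <- train_ids[vapply(train_ids, length, integer(1)) > 0]

    # --- per-dataset feature filtration on training rows ----------------
    train_feats <- lapply(names(train_ids), function(d) {
      src <- if (d %in% names(datasets)) d else config$variant
      align_features(feat_of(src)[train_ids[[d]], , drop = FALSE], universe)
    })
    if (ps == "taxonomy") {
      retained <- filter_taxonomic_features(train_feats)
    } else {
      train_pads <- lapply(names(train_ids), function(d) {
        align_features(datasets[[d]]$pad[train_ids[[d]], , drop = FALSE],
                       universe)
      })
      retained <- filter_phenotype_features(train_feats, train_pads)
    }
    if (length(retained) == 0L)
      stop("feature filtration retained no features (", config$strategy, ":",
           config$variant, ", iteration ", i, ")")

    # --- extraction and final fit --------------------------------------
    x_train <- do.call(rbind, train_feats)[, retained, drop = FALSE]
    y_train <- unlist(lapply(names(train_ids), function(d)
      lab_of(d)[train_ids[[d]]]), use.names = FALSE)
    if (!all(classes %in% y_train))
      stop("class absent from training fold: ",
           paste(setdiff(classes, y_train), collapse = ", "))
    top <- extract_top_features(x_train, y_train, config$rf,
                                n_sub = config$n_sub, top_k = config$top_k,
                                seed = derive_seed(seed_i, 3))
    fit <- fit_rf(x_train[, top, drop = FALSE], y_train, config$rf,
                  seed = derive_seed(seed_i, 4))

    # --- evaluation -----------------------------------------------------
    if (config$strategy == "Mixed") {
      all_feats <- do.call(rbind, lapply(names(datasets), function(d)
        align_features(feat_of(d), universe)))
      all_labs <- unlist(lapply(names(datasets), lab_of))
      names(all_labs) <- rownames(all_feats)
      x_test <- all_feats[test_ids[[1]], top, drop = FALSE]
      y_test <- all_labs[test_ids[[1]]]
    } else {
      d <- names(test_ids)[1]
      x_test <- align_features(feat_of(d)[test_ids[[1]], , drop = FALSE],
                               universe)[, top, drop = FALSE]
      y_test <- lab_of(d)[test_ids[[1]]]
    }
    prob <- predict_prob(fit, x_test, positive)
    roc <- pROC::roc(response = factor(y_test, levels = classes),
                     predictor = prob, levels = classes, direction = "<",
                     quiet = TRUE)
    pred_pos <- prob >= threshold
    is_pos <- y_test == positive
    imp <- fit$variable.importance
    if (sum(imp) > 0) imp <- imp / sum(imp)
    importances <- stats::setNames(numeric(length(universe)), universe)
    importances[names(imp)] <- imp
    results[[i]] <- list(
      auc = as.numeric(pROC::auc(roc)),
      sensitivity = if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_,
      specificity = if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_,
      features = top,
      importances = importances,
      n_train = length(y_train), n_test = length(y_test))
  }
  attr(results, "universe") <- universe
  attr(results, "config") <- config
  results
}

#' Run the full strategy suite for one predictor set and contrast
#'
#' Executes all dataset-division variants (Single per cohort, L1O per
#' held-out cohort, Mixed; 7 variants for three cohorts) for one predictor
#' set and disease contrast, and aggregates per-variant mean feature
#' importances. A feature not extracted in every iteration of a variant gets
#' importance 0 for that variant. Per-dataset case-minus-control mean feature
#' differences (computed on the full cohorts) accompany the importances for
#' stable-predictor analysis.
#'
#' @inheritParams train_and_evaluate
#' @param predictor_set `"taxonomy"` or `"phenotype"`.
#' @param contrast `"CD"` or `"UC"`.
#' @param rf an [rf_params()] object.
#' @param seed master seed.
#' @param n_iterations_single,n_iterations_l1o,n_sub,top_k see
#'   [enumerate_configs()].
#' @return list with `variant_importances` (variants x features),
#'   `group_diffs` (datasets x features, case mean minus HC mean), `metrics`
#'   (per-variant mean/sd of AUC, sensitivity, specificity) and `results`
#'   (per-variant iteration results).
#' @export
run_variant_suite <- function(datasets, predictor_set, contrast,
                              rf = rf_params(), seed = 1,
                              n_iterations_single = 10, n_iterations_l1o = 3,
                              n_sub = 10, top_k = 20) {
  configs <- enumerate_configs(names(datasets),
                               predictor_sets = predictor_set,
                               contrasts = contrast, rf = rf,
                               n_iterations_single = n_iterations_single,
                               n_iterations_l1o = n_iterations_l1o,
                               n_sub = n_sub, top_k = top_k, seed = seed)
  results <- lapply(configs, train_and_evaluate, datasets = datasets)
  names(results) <- vapply(configs, function(cf)
    paste0(cf$strategy, ":", cf$variant), character(1))

  universe <- sort(unique(unlist(lapply(results, attr, "universe"))))
  variant_importances <- t(vapply(results, function(res) {
    im <- vapply(res, function(r) {
      v <- stats::setNames(numeric(length(universe)), universe)
      v[names(r$importances)] <- r$importances
      v
    }, numeric(length(universe)))
    im <- matrix(im, nrow = length(universe))
    ifelse(apply(im > 0, 1, all), rowMeans(im), 0)
  }, numeric(length(universe))))
  colnames(variant_importances) <- universe

  group_diffs <- t(vapply(names(datasets), function(d) {
    feats <- align_features(datasets[[d]][[predictor_set]], universe)
    lab <- datasets[[d]]$labels
    case <- colMeans(feats[names(lab)[lab == contrast], , drop = FALSE])
    ctrl <- colMeans(feats[names(lab)[lab == "HC"], , drop = FALSE])
    case - ctrl
  }, numeric(length(universe))))
  colnames(group_diffs) <- universe

  metrics <- do.call(rbind, lapply(names(results), function(nm) {
    res <- results[[nm]]
    data.frame(variant = nm,
               strategy = sub(":.*", "", nm),
               mean_auc = mean(vapply(res, `[[`, numeric(1), "auc")),
               sd_auc = stats::sd(vapply(res, `[[`, numeric(1), "auc")),
               mean_sensitivity = mean(vapply(res, `[[`, numeric(1),
                                              "sensitivity"), na.rm = TRUE),
               mean_specificity = mean(vapply(res, `[[`, numeric(1),
                                              "specificity"), na.rm = TRUE))
  }))
  list(variant_importances = variant_importances, group_diffs = group_diffs,
       metrics = metrics, results = results)
}
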