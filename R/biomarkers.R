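#' Identify stable predictors across classifier variants
#'
#' A feature is a stable predictor for a disease contrast when (i) it has a
#' nonzero mean importance in at least `min_variants` of the strategy-by-
#' dataset classifier variants (6 of 7 with three cohorts) and (ii) the sign
#' of its case-minus-control mean difference is the same, and nonzero, in
#' every dataset. The reported importance is the average across all
#' variants (zeros included).
#'
#' @param variant_importances variants x features matrix of per-variant mean
#'   importances, 0 for features not extracted in every iteration of a
#'   variant (as produced by [run_variant_suite()]).
#' @param group_diffs datasets x features matrix of case-minus-control mean
#'   feature differences.
#' @param min_variants minimal number of variants with nonzero importance
#'   (default: one less than the number of variants, i.e. 6 of 7).
#' @return data.frame (`feature`, `mean_importance`, `direction`,
#'   `n_variants_nonzero`) of stable predictors, sorted by decreasing mean
#'   importance; `direction` is +1 for case-enriched, -1 for case-depleted.
#' @export
identify_stable_predictors <- function(variant_importances, group_diffs,
                                       min_variants = nrow(variant_importances) - 1L) {
  features <- colnames(variant_importances)
  stopifnot(all(features %in% colnames(group_diffs)))
  n_nonzero <- colSums(variant_importances > 0)
  signs <- sign(group_diffs[, features, drop = FALSE])
  consistent <- apply(signs, 2, function(s) all(s == 1) || all(s == -1))
  stable <- n_nonzero >= min_variants & consistent
  out <- data.frame(
    feature = features[stable],
    mean_importance = colMeans(variant_importances[, stable, drop = FALSE]),
    direction = as.integer(signs[1, features[stable]]),
    n_variants_nonzero = as.integer(n_nonzero[stable]),
    row.names = NULL)
  out[order(-out$mean_importance, out$feature), , drop = FALSE]
}

#' Single-feature partial dependence curve
#'
#' Computes the model-predicted disease probability as a function of one
#' feature: the feature column is substituted with each grid value in every
#' training row and the predicted positive-class probabilities are averaged.
#' The grid spans the observed training range of the feature in `n_grid`
#' equally spaced steps (endpoints included) unless given explicitly.
#'
#' @param model a fitted probability forest (from the pipeline), or any
#'   function mapping a feature matrix to positive-class probabilities.
#' @param train_x training samples x features matrix.
#' @param feature feature name.
#' @param positive positive class label (ignored when `model` is a function).
#' @param grid explicit grid values (overrides `n_grid`).
#' @param n_grid number of grid steps (default 20).
#' @return list of class `"pdp_curve"` with `feature`, `grid` and `prob`.
#' @export
compute_pdp <- function(model, train_x, feature, positive = "CD",
                        grid = NULL, n_grid = 20) {
  stopifnot(feature %in% colnames(train_x))
  if (is.null(grid)) {
    rng <- range(train_x[, feature])
    if (diff(rng) == 0)
      stop("feature '", feature, "' is constant in the training data; ",
           "partial dependence is undefined")
    grid <- seq(rng[1], rng[2], length.out = n_grid)
  }
  predict_fun <- if (is.function(model)) model else
    function(x) predict_prob(model, x, positive)
  prob <- vapply(grid, function(g) {
    x <- train_x
    x[, feature] <- g
    mean(predict_fun(x))
  }, numeric(1))
  structure(list(feature = feature, grid = grid, prob = prob),
            class = "pdp_curve")
}

#' Average partial dependence curves over iterations
#'
#' Pointwise mean of curves computed on a common grid.
#'
#' @param curves list of `"pdp_curve"` objects with identical grids.
#' @return a `"pdp_curve"` with the mean probabilities.
#' @export
average_pdp <- function(curves) {
  stopifnot(length(curves) >= 1)
  g <- curves[[1]]$grid
  for (cv in curves) stopifnot(isTRUE(all.equal(cv$grid, g)))
  structure(list(feature = curves[[1]]$feature, grid = g,
                 prob = rowMeans(vapply(curves, `[[`, numeric(length(g)),
                                        "prob"))),
            class = "pdp_curve")
}

#' Classify the form of a partial dependence curve
#'
#' Labels a 20-step partial dependence curve as sharply/smoothly
#' increasing/decreasing or unclassified from the probability differences
#' `delta_i = prob[i + 5] - prob[i]` for `i = 1..15`:
#'
#' * Direction is the sign of the `delta_i` with the largest absolute value.
#'   If positive and negative deltas both occur and the ratio of the largest
#'   absolute values of the two signs (larger over smaller) is below 2, the
#'   curve is unclassified; a flat curve (all deltas zero) is unclassified
#'   too.
#' * The form is sharp when at least one `|delta_i|` is at least three times
#'   the larger of the probability ranges (max minus min) over the outer
#'   lower interval `[1, i)` and outer upper interval `(i+5, 20]` (an empty
#'   or singleton interval contributes range 0); otherwise it is smooth.
#'
#' @param curve a `"pdp_curve"` or a numeric vector of 20 probabilities.
#' @return one of `"sharply_decreasing"`, `"sharply_increasing"`,
#'   `"smoothly_decreasing"`, `"smoothly_increasing"`, `"unclassified"`.
#' @export
classify_pdp_form <- function(curve) {
  prob <- if (inherits(curve, "pdp_curve")) curve$prob else as.numeric(curve)
  if (length(prob) != 20L)
    stop("PDP form classification expects a 20-step curve")
  i <- 1:15
  deltas <- prob[i + 5L] - prob[i]
  if (all(deltas == 0)) return("unclassified")
  pos <- deltas[deltas > 0]
  neg <- deltas[deltas < 0]
  if (length(pos) && length(neg)) {
    hi <- max(max(abs(pos)), max(abs(neg)))
    lo <- min(max(abs(pos)), max(abs(neg)))
    if (hi / lo < 2) return("unclassified")
  }
  direction <- if (sign(deltas[which.max(abs(deltas))]) > 0)
    "increasing" else "decreasing"
  outer_range <- function(idx) if (length(idx) < 2L) 0 else
    max(prob[idx]) - min(prob[idx])
  sharp <- any(vapply(i, function(k) {
    outer <- max(outer_range(seq_len(k - 1L)),
                 outer_range(seq2(k + 6L, 20L)))
    abs(deltas[k]) > 0 && abs(deltas[k]) >= 3 * outer
  }, logical(1)))
  paste0(if (sharp) "sharply_" else "smoothly_", direction)
}

# seq() that returns integer(0) when from > to (base seq would count down).
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Partial dependence analysis of stable predictors
#'
#' Re-trains Mixed-strategy classifiers restricted to the stable predictors
#' (per-cohort equalized subsample and stratified two-thirds split redrawn
#' each iteration) and computes, for every predictor, the partial dependence
#' curve of each iteration's forest on a grid spanning the union of the
#' iterations' training ranges. Iteration curves are averaged pointwise and
#' the mean curve's form is classified with [classify_pdp_form()].
#'
#' @param datasets as in [train_and_evaluate()].
#' @param features character vector of stable predictor names.
#' @param predictor_set `"taxonomy"` or `"phenotype"`.
#' @param contrast `"CD"` or `"UC"`.
#' @param rf an [rf_params()] object.
#' @param n_iterations number of cross-validation iterations (default 20).
#' @param n_grid grid resolution (default 20).
#' @param seed master seed.
#' @return data.frame (`feature`, `form`) plus the mean curves in attribute
#'   `"curves"`.
#' @export
stable_predictor_pdps <- function(datasets, features, predictor_set, contrast,
                                  rf = rf_params(), n_iterations = 20,
                                  n_grid = 20, seed = 1) {
  stopifnot(length(features) >= 1)
  classes <- c("HC", contrast)
  fits <- vector("list", n_iterations)
  trains <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    seed_i <- derive_seed(seed, 9, i)
    labs <- lapply(datasets, function(x) {
      l <- x$labels
      l[l %in% classes]
    })
    sub <- subsample_equalize(labs, statuses = classes,
                              seed = derive_seed(seed_i, 1))
    x <- do.call(rbind, lapply(names(datasets), function(d)
      align_features(datasets[[d]][[predictor_set]][sub$ids[[d]], ,
                                                    drop = FALSE], features)))
    y <- unlist(lapply(names(datasets), function(d)
      datasets[[d]]$labels[sub$ids[[d]]]), use.names = FALSE)
    sp <- split_stratified(y, seed = derive_seed(seed_i, 2))
    trains[[i]] <- x[sp$train, , drop = FALSE]
    fits[[i]] <- fit_rf(trains[[i]], y[sp$train], rf,
                        seed = derive_seed(seed_i, 3))
  }
  curves <- lapply(features, function(f) {
    rng <- range(unlist(lapply(trains, function(tx) range(tx[, f]))))
    if (diff(rng) == 0)
      stop("stable predictor '", f, "' is constant across training sets")
    grid <- seq(rng[1], rng[2], length.out = n_grid)
    average_pdp(lapply(seq_len(n_iterations), function(i)
      compute_pdp(fits[[i]], trains[[i]], f, positive = contrast,
                  grid = grid)))
  })
  names(curves) <- features
  out <- data.frame(feature = features,
                    form = vapply(curves, classify_pdp_form, character(1)),
                    row.names = NULL)
  attr(out, "curves") <- curves
  out
}
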