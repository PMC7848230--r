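test_that("configuration enumeration matches the closed form", {
  cfgs <- enumerate_configs(c("ESP", "NLD", "CHN"))
  expect_length(cfgs, 28)
  strat <- vapply(cfgs, function(cf) paste0(cf$strategy, ":", cf$variant),
                  character(1))
  expect_length(unique(strat), 7)
  contrast <- vapply(cfgs, `[[`, character(1), "contrast")
  expect_equal(unname(table(contrast)), c(14L, 14L), ignore_attr = TRUE)

  expect_length(enumerate_configs("ESP"), 4)
  expect_length(enumerate_configs(c("A", "B")), 20)
  # (2n + 1) * |predictor sets| * |contrasts| for n >= 2
  for (n in 2:5)
    expect_length(enumerate_configs(paste0("d", 1:n)), (2 * n + 1) * 4)
})

test_that("L1O iteration counts differ from Single/Mixed", {
  cfgs <- enumerate_configs(c("A", "B", "C"), predictor_sets = "taxonomy",
                            contrasts = "CD")
  n_it <- vapply(cfgs, `[[`, numeric(1), "n_iterations")
  strat <- vapply(cfgs, `[[`, character(1), "strategy")
  expect_true(all(n_it[strat == "L1O"] == 3))
  expect_true(all(n_it[strat != "L1O"] == 10))
})

test_that("subsampling equalizes per-status counts at the cross-dataset minimum", {
  labs <- list(ESP = labels_from_counts(c(HC = 91, CD = 34, UC = 39), "E"),
               NLD = labels_from_counts(c(HC = 496, CD = 163, UC = 99), "N"),
               CHN = labels_from_counts(c(HC = 67, CD = 50, UC = 37), "C"))
  sub <- subsample_equalize(labs, seed = 1)
  expect_equal(sub$targets, c(CD = 34, HC = 67, UC = 37))
  for (d in names(labs)) {
    drawn <- table(labs[[d]][sub$ids[[d]]])
    expect_equal(unname(drawn[names(sub$targets)]), unname(sub$targets),
                 ignore_attr = TRUE)
    expect_false(anyDuplicated(sub$ids[[d]]) > 0)
  }
  # L1O training pair: CD counts (50, 163) -> 50 each
  pair <- subsample_equalize(labs[c("CHN", "NLD")], statuses = c("HC", "CD"))
  expect_equal(pair$targets, c(CD = 50, HC = 67))
  # equal counts: a no-op beyond shuffling
  eq <- subsample_equalize(list(a = labels_from_counts(c(HC = 37), "a"),
                                b = labels_from_counts(c(HC = 37), "b")))
  expect_equal(unname(eq$targets), 37)
  expect_length(eq$ids$a, 37)
})

test_that("taxonomic feature filtration drops sparse and low features", {
  n <- 40
  tb <- matrix(0, n, 3, dimnames = list(sprintf("s%02d", 1:n),
                                        c("sparse", "low", "good")))
  tb[1:4, "sparse"] <- 0.05      # nonzero in only 4 samples
  tb[, "low"] <- 0.009           # max below 1%
  tb[, "good"] <- 0.05
  expect_equal(filter_taxonomic_features(list(tb)), "good")
  # rules must hold in each dataset separately
  tb2 <- tb
  tb2[, "good"] <- 0.009
  expect_length(filter_taxonomic_features(list(tb, tb2)), 0)
  # idempotent / order-independent
  expect_equal(filter_taxonomic_features(list(tb2, tb)),
               filter_taxonomic_features(list(tb, tb2)))
})

test_that("phenotype feature filtration applies CPI and PAD rules", {
  n <- 30
  cpi <- cbind(high = rep(0.95, n), rare = c(rep(0.5, 4), rep(0.01, n - 4)),
               good = rep(0.5, n))
  rownames(cpi) <- sprintf("s%02d", 1:n)
  pad <- cbind(high = rep(6, n), rare = rep(6, n), good = rep(6, n))
  rownames(pad) <- rownames(cpi)
  expect_equal(filter_phenotype_features(list(cpi), list(pad)), "good")
  # mean PAD below 3.5 drops a phenotype
  pad2 <- pad
  pad2[, "good"] <- 3.4
  expect_length(filter_phenotype_features(list(cpi), list(pad2)), 0)
  # boundary: mean CPI exactly 0.9 is retained (closed interval)
  cpi3 <- cbind(edge = rep(0.9, n))
  rownames(cpi3) <- rownames(cpi)
  pad3 <- cbind(edge = rep(4, n))
  rownames(pad3) <- rownames(cpi)
  expect_equal(filter_phenotype_features(list(cpi3), list(pad3)), "edge")
})

test_that("feature extraction ranks a perfect separator first", {
  set.seed(13)
  n <- 60
  y <- rep(c("HC", "CD"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  x[, "f01"] <- ifelse(y == "CD", 1, 0) + rnorm(n, 0, 0.01)
  top <- extract_top_features(x, y, seed = 5)
  expect_length(top, 10)           # top_k = 20 > 10 features: all returned
  expect_equal(top[1], "f01")
  # all-constant features: zero importance, lexicographic order
  xc <- matrix(1, n, 3, dimnames = list(NULL, c("b", "a", "c")))
  expect_equal(extract_top_features(xc, y, seed = 5), c("a", "b", "c"))
})

test_that("balanced class weights follow n / (k * n_c)", {
  w <- balanced_class_weights(rep(c("CD", "HC"), c(10, 30)))
  expect_equal(w[["CD"]], 2)
  expect_equal(w[["HC"]], 2 / 3)
  expect_error(fit_rf(matrix(rnorm(10), 5, 2,
                             dimnames = list(NULL, c("a", "b"))),
                      rep("HC", 5), rf_params(), seed = 1),
               "single class")
})

test_that("a perfectly separable dataset yields AUC 1 and is reproducible", {
  set.seed(17)
  n <- 90
  lab <- setNames(rep(c("HC", "CD", "UC"), each = n / 3),
                  sprintf("s%03d", 1:n))
  feats <- matrix(abs(rnorm(n * 8, 0.05, 0.02)), n, 8,
                  dimnames = list(names(lab), sprintf("f%d", 1:8)))
  feats[, "f1"] <- ifelse(lab == "CD", 0.5, 0.02)
  feats <- feats / rowSums(feats)
  ds <- list(one = list(taxonomy = feats, labels = lab))
  cfg <- classifier_config("Single", "one", "taxonomy", "CD",
                           n_iterations = 3, n_sub = 3, seed = 9)
  res <- train_and_evaluate(cfg, ds)
  expect_equal(vapply(res, `[[`, numeric(1), "auc"), rep(1, 3))
  expect_true(all(vapply(res, function(r) "f1" %in% r$features, logical(1))))
  res2 <- train_and_evaluate(cfg, ds)
  expect_identical(lapply(res, `[[`, "importances"),
                   lapply(res2, `[[`, "importances"))
})

test_that("iteration importances cover the universe with zeros elsewhere", {
  set.seed(19)
  n <- 60
  lab <- setNames(rep(c("HC", "CD"), each = n / 2), sprintf("s%03d", 1:n))
  feats <- matrix(abs(rnorm(n * 6, 0.2, 0.05)), n, 6,
                  dimnames = list(names(lab), sprintf("g%d", 1:6)))
  feats <- feats / rowSums(feats)
  ds <- list(one = list(taxonomy = feats, labels = lab))
  cfg <- classifier_config("Single", "one", "taxonomy", "CD",
                           n_iterations = 2, n_sub = 2, top_k = 3, seed = 2)
  res <- train_and_evaluate(cfg, ds)
  for (r in res) {
    expect_setequal(names(r$importances), colnames(feats))
    expect_true(all(r$importances >= 0))
    expect_length(r$features, 3)
    expect_true(all(r$importances[setdiff(colnames(feats), r$features)] == 0))
    expect_equal(sum(r$importances), 1, tolerance = 1e-9)
  }
})
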