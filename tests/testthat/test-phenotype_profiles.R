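test_that("rare-ASV filter applies the three retention criteria", {
  # 100 samples; asvA present once at 0.006 (max rule), asvB present twice at
  # 0.001 (prevalence rule: 2% > 0.5%), filler takes the remainder
  n <- 100
  a <- matrix(0, n, 3, dimnames = list(sprintf("s%03d", 1:n),
                                       c("asvA", "asvB", "filler")))
  a[1, "asvA"] <- 0.006
  a[2:3, "asvB"] <- 0.001
  a[, "filler"] <- 1 - rowSums(a)
  ds <- filter_asv_table(toy_dataset(a))
  expect_setequal(colnames(ds$abundance), c("asvA", "asvB", "filler"))
  expect_equal(unname(rowSums(ds$abundance)), rep(1, n))

  # 1000 samples; asvC present once at 0.001 (mean 1e-6) fails all rules
  n <- 1000
  a <- matrix(0, n, 2, dimnames = list(sprintf("s%04d", 1:n),
                                       c("asvC", "filler")))
  a[1, "asvC"] <- 0.001
  a[, "filler"] <- 1 - rowSums(a)
  ds <- filter_asv_table(toy_dataset(a))
  expect_equal(colnames(ds$abundance), "filler")

  # abundances renormalize after dropping an ASV
  expect_equal(unname(ds$abundance[1, "filler"]), 1)
})

test_that("coverage filter is strictly greater-than", {
  a <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("x", "y")))
  reads <- c(s1 = 15000, s2 = 15001, s3 = 4001)
  ds <- toy_dataset(a, reads = reads)
  expect_equal(rownames(filter_by_coverage(ds, 15000)$abundance), "s2")
  expect_equal(rownames(filter_by_coverage(ds, 4000)$abundance),
               c("s1", "s2", "s3"))
  expect_equal(rownames(filter_by_coverage(ds, 0)$abundance),
               rownames(a))
})

test_that("phenotype probabilities are mapping-weighted BPM averages", {
  b <- bpm(matrix(c(1, 1, 0, 0, 1, 0, 0, 0), 4, 2,
                  dimnames = list(paste0("g", 1:4), c("pA", "pB"))))
  maps <- list(asv1 = c(g1 = 0.5, g2 = 0.5),        # {1,1} -> 1
               asv2 = c(g1 = 0.5, g3 = 0.5),        # {1,0} -> 0.5
               asv3 = c(g1 = 0.25, g2 = 0.25, g3 = 0.25, g4 = 0.25))
  p <- phenotype_probability(maps, b)
  expect_equal(p["asv1", "pA"], 1)
  expect_equal(p["asv2", "pA"], 0.5)
  expect_equal(p["asv3", "pA"], 0.5)
  expect_equal(p["asv3", "pB"], 0.25)
  expect_error(phenotype_probability(list(a = c(gX = 1)), b),
               "absent from BPM: gX")
})

test_that("CPI is the abundance-weighted carriage probability", {
  p <- matrix(c(1, 0), 2, 1, dimnames = list(c("a1", "a2"), "ph"))
  a <- matrix(c(0.3, 0.7), 1, 2, dimnames = list("s", c("a1", "a2")))
  expect_equal(compute_cpi(a, p)[1, 1], 0.3)

  p2 <- matrix(c(0.5, 0.25), 2, 1, dimnames = list(c("a1", "a2"), "ph"))
  a2 <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("s", c("a1", "a2")))
  expect_equal(compute_cpi(a2, p2)[1, 1], 0.35)

  # all-ones phenotype: CPI equals total mapped abundance
  p3 <- matrix(1, 2, 1, dimnames = list(c("a1", "a2"), "ph"))
  a3 <- matrix(c(0.2, 0.5, 0.3), 1, 3,
               dimnames = list("s", c("a1", "a2", "unmapped")))
  expect_equal(compute_cpi(a3, p3)[1, 1], 0.7)
})

test_that("CPI satisfies complement, linearity and permutation invariance", {
  set.seed(3)
  asvs <- paste0("a", 1:20)
  p <- matrix(rbinom(20, 1, 0.5), 20, 1, dimnames = list(asvs, "ph"))
  a <- matrix(rexp(20), 1, 20, dimnames = list("s", asvs))
  a <- a / sum(a)
  # binary p with every ASV mapped: CPI(ph) + CPI(1 - ph) = 1
  expect_equal(compute_cpi(a, p)[1, 1] + compute_cpi(a, 1 - p)[1, 1], 1)
  # permutation invariance
  perm <- sample(asvs)
  expect_equal(compute_cpi(a[, perm, drop = FALSE], p)[1, 1],
               compute_cpi(a, p)[1, 1])
  # linearity in abundances
  a2 <- matrix(rexp(20), 1, 20, dimnames = list("s", asvs))
  expect_equal(compute_cpi(a + a2, p)[1, 1],
               compute_cpi(a, p)[1, 1] + compute_cpi(a2, p)[1, 1])
})

test_that("built-in tree recovers 2-tip symmetry and 4-tip topology", {
  seqs <- c(t1 = strrep("A", 40), t2 = paste0(strrep("A", 36), "CCCC"))
  tr <- build_tree(seqs)
  expect_setequal(tr$tip.label, c("t1", "t2"))
  d <- ape::cophenetic.phylo(tr)["t1", "t2"]
  h <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(unname(h), rep(d / 2, 2))

  # sequences simulated along a known 4-taxon tree with strong signal
  true <- ape::read.tree(text = "((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2);")
  set.seed(5)
  sim <- phangorn::simSeq(true, l = 2000, type = "DNA")
  m <- toupper(as.character(sim))
  seqs4 <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  got <- build_tree(seqs4)
  expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(true)), 0)
})

test_that("midpoint rooting bisects the longest tip-to-tip path", {
  tr <- midpoint_root(ape::read.tree(text = "(a:3,b:1);"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[match("a", tr$tip.label)], 2)
  expect_equal(depths[match("b", tr$tip.label)], 2)

  set.seed(11)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:10, 1), rooted = FALSE)
    rooted <- midpoint_root(tr)
    expect_true(ape::is.rooted(rooted))
    expect_setequal(rooted$tip.label, tr$tip.label)
    # max root-to-tip distance equals half the tree diameter, the minimum
    # achievable over all root placements
    ntip <- length(rooted$tip.label)
    depths <- ape::node.depth.edgelength(rooted)[seq_len(ntip)]
    diam <- max(ape::cophenetic.phylo(rooted))
    expect_equal(max(depths), diam / 2, tolerance = 1e-9)
  }
})

test_that("faith_pd matches the brute-force union-of-root-paths oracle", {
  tr <- ape::read.tree(
    text = "((A:1,B:2):0.5,(C:0.25,D:0.25):3);")
  expect_equal(faith_pd(tr, character(0)), 0)
  expect_equal(faith_pd(tr, "A"), 1.5)
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
  expect_equal(faith_pd(tr, c("A", "C")), 1 + 0.5 + 0.25 + 3)

  set.seed(21)
  for (i in 1:10) {
    tr <- midpoint_root(ape::rtree(sample(4:8, 1)))
    tips <- tr$tip.label
    for (k in seq_along(tips)) {
      for (draw in 1:3) {
        sub <- sample(tips, k)
        expect_equal(faith_pd(tr, sub), brute_pd(tr, sub))
      }
    }
    # monotone: adding a tip never decreases PD
    sub <- sample(tips, 2)
    extra <- sample(setdiff(tips, sub), 1)
    expect_gte(faith_pd(tr, c(sub, extra)), faith_pd(tr, sub))
  }
})

test_that("faith_pd agrees with picante's root-inclusive PD", {
  skip_if_not_installed("picante")
  set.seed(31)
  tr <- midpoint_root(ape::rtree(12))
  comm <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
                 dimnames = list(paste0("s", 1:5), tr$tip.label))
  comm[1, ] <- 1
  ours <- apply(comm, 1, function(v) faith_pd(tr, names(v)[v == 1]))
  theirs <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(unname(ours), theirs, tolerance = 1e-9)
})

test_that("PAD uses strict carrier threshold and presence in sample", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:0.25,D:0.25):3);")
  p <- matrix(c(1, 0.6, 0, 0), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "ph"))
  a <- matrix(c(0.5, 0.5, 0, 0), 1, 4,
              dimnames = list("s1", c("A", "B", "C", "D")))
  pad <- compute_pad(a, p, tr)
  # B is at exactly 0.6: excluded; PAD is A's root path
  expect_equal(pad["s1", "ph"], 1.5)
  # carrier absent from the sample: PAD 0
  a2 <- matrix(c(0, 0.5, 0.25, 0.25), 1, 4,
               dimnames = list("s2", c("A", "B", "C", "D")))
  expect_equal(compute_pad(a2, p, tr)["s2", "ph"], 0)
  # PAD equals faith_pd of present carriers for a multi-carrier phenotype
  p2 <- matrix(c(1, 0.9, 0.7, 0), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), "ph2"))
  a3 <- matrix(c(0.3, 0, 0.4, 0.3), 1, 4,
               dimnames = list("s3", c("A", "B", "C", "D")))
  expect_equal(compute_pad(a3, p2, tr)["s3", "ph2"],
               faith_pd(tr, c("A", "C")))
})
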