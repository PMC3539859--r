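test_that("fragment classes match a brute-force per-fragment scan", {
  for (seed in 1:5) {
    mm <- random_marker(10, 25, p_missing = 0.1, seed = seed)
    grouping <- setNames(rep(c("A", "B"), each = 5), rownames(mm))
    fc <- fragment_classes(mm, grouping)
    m <- unclass(mm)
    for (g in c("A", "B")) {
      inside <- m[names(grouping)[grouping == g], , drop = FALSE]
      outside <- m[names(grouping)[grouping != g], , drop = FALSE]
      polym <- fixed <- priv <- 0
      for (l in seq_len(ncol(m))) {
        v <- inside[, l][!is.na(inside[, l])]
        o <- outside[, l][!is.na(outside[, l])]
        if (any(v == 1) && any(v == 0)) polym <- polym + 1
        if (length(v) > 0 && all(v == 1)) fixed <- fixed + 1
        if (any(v == 1) && !any(o == 1)) priv <- priv + 1
      }
      row <- fc[fc$group == g, ]
      expect_equal(row$frag_polymorphic, polym)
      expect_equal(row$frag_fixed, fixed)
      expect_equal(row$frag_private, priv)
    }
  }
})

test_that("261 polymorphic of 294 loci is 88.78%", {
  band <- matrix(0L, 2, 294)
  band[2, 1:261] <- 1L          # 261 loci differ between the two samples
  band[, 262:294] <- 1L         # remaining 33 fixed
  mm <- marker_matrix(band)
  fc <- fragment_classes(mm, setNames(c("all", "all"), rownames(mm)))
  expect_equal(fc$frag_polymorphic, 261)
  expect_equal(round(fc$pct_polymorphic, 2), 88.78)
})

test_that("degenerate groupings behave: single-sample and disjoint groups", {
  mm <- marker_matrix(rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1),
                            c = c(0, 0, 1, 0)))
  fc1 <- fragment_classes(mm, c(a = "solo", b = "rest", c = "rest"))
  solo <- fc1[fc1$group == "solo", ]
  expect_equal(solo$frag_polymorphic, 0)
  expect_equal(solo$frag_fixed, 2)        # its two present fragments
  # disjoint band sets -> every present fragment private to its group
  expect_equal(solo$frag_private, 2)
  expect_equal(fc1$frag_private[fc1$group == "rest"], 2)
  expect_error(fragment_classes(mm, c(a = "g")), NA)
  expect_error(as_grouping(c(zz = "g"), rownames(mm), "population"),
               "no sample")
})

test_that("rare fragments are classified by area-specificity and a frequency threshold", {
  # 10 native, 10 introduced samples
  band <- matrix(0L, 20, 4)
  band[1, 1] <- 1L                  # native-specific at freq 0.1 -> rare
  band[1:2, 2] <- 1L                # native-specific at 0.2 -> common
  band[c(1, 11), 3] <- 1L           # shared, rare in both (0.1 / 0.1)
  band[, 4] <- 1L                   # shared, fixed
  mm <- marker_matrix(band)
  areas <- setNames(rep(c("native", "introduced"), each = 10),
                    rownames(mm))
  rf <- rare_fragments(mm, areas, threshold = 0.15)
  pf <- rf$per_fragment
  expect_equal(pf$specificity, c("native-specific", "native-specific",
                                 "shared", "shared"))
  expect_equal(pf$rare, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(rare_fragments(mm, areas, threshold = 0), "threshold")
})

test_that("a planted 40-of-45 rare share among area-specific fragments is recovered", {
  # 20 native samples; 45 native-only fragments, 40 at frequency 0.10 and
  # 5 at 0.30; introduced samples carry none of them
  n_nat <- 20; n_int <- 20
  band <- matrix(0L, n_nat + n_int, 45)
  for (l in 1:40) band[sample(1:n_nat, 2), l] <- 1L
  for (l in 41:45) band[sample(1:n_nat, 6), l] <- 1L
  filler <- matrix(1L, n_nat + n_int, 2)  # keep introduced rows scored
  mm <- marker_matrix(cbind(band, filler))
  areas <- setNames(rep(c("native", "introduced"), c(n_nat, n_int)),
                    rownames(mm))
  rf <- rare_fragments(mm, areas, threshold = 0.15)
  spec <- rf$per_fragment[rf$per_fragment$specificity == "native-specific", ]
  expect_equal(nrow(spec), 45)
  expect_equal(sum(spec$rare), 40)
  expect_equal(round(100 * mean(spec$rare)), 89)
})

test_that("gene diversity follows the unbiased two-state formula", {
  # monomorphic -> 0
  mono <- marker_matrix(matrix(1L, 4, 6))
  h <- gene_diversity_hj(mono, n_boot = 50, seed = 1)
  expect_equal(h$hj, 0)
  expect_equal(h$sd, 0)
  # one locus, p = 0.5, n = 2: the n/(n-1) correction gives h = 1.0
  two <- marker_matrix(rbind(a = c(1L), b = c(0L)))
  expect_equal(gene_diversity_hj(two, n_boot = 0)$hj, 1.0)
  # hand-checked mixed case: per-locus h averaged over loci
  m <- marker_matrix(rbind(a = c(1, 1, 0), b = c(0, 1, 0), c = c(1, 1, 1)))
  # locus-wise p = 2/3, 1, 1/3; h = 1.5*(1-p^2-q^2)
  hl <- 3 / 2 * (1 - c((2/3)^2 + (1/3)^2, 1, (1/3)^2 + (2/3)^2))
  expect_equal(gene_diversity_hj(m, n_boot = 0)$hj, mean(hl))
  expect_error(gene_diversity_hj(marker_matrix(matrix(1L, 1, 3))),
               "at least 2")
})

test_that("gene diversity is invariant to presence/absence relabelling", {
  mm <- random_marker(8, 30, seed = 4)
  flipped <- marker_matrix(1L - unclass(mm))
  expect_equal(gene_diversity_hj(mm, n_boot = 0)$hj,
               gene_diversity_hj(flipped, n_boot = 0)$hj)
})

test_that("estimated diversity tracks the generating presence probabilities", {
  set.seed(21)
  p <- runif(60, 0.05, 0.95)
  n <- 40
  band <- sapply(p, function(pr) rbinom(n, 1, pr))
  mm <- marker_matrix(band)
  h <- gene_diversity_hj(mm, n_boot = 500, seed = 2)
  expected <- mean(2 * p * (1 - p))   # unbiased estimator targets 2pq
  expect_lt(abs(h$hj - expected), 4 * h$sd)
})

test_that("duplicating a sample never increases the polymorphic count", {
  for (seed in 1:3) {
    mm <- random_marker(6, 15, seed = seed)
    grouping <- setNames(rep("g", 6), rownames(mm))
    before <- fragment_classes(mm, grouping)$frag_polymorphic
    dup <- marker_matrix(rbind(unclass(mm), s_dup = unclass(mm)[1, ]))
    after <- fragment_classes(dup, setNames(rep("g", 7),
                                            rownames(dup)))$frag_polymorphic
    expect_lte(after, before)
  }
})
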