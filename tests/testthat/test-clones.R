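test_that("error rate follows the mismatches / (pairs x loci) definition", {
  er <- error_rate(123, 9, 294)
  expect_equal(er$rate, 123 / (9 * 294))
  expect_equal(round(100 * er$rate, 2), 4.65)
  # identical replicates give zero
  m <- marker_matrix(rbind(a = c(1, 0, 1), a_r = c(1, 0, 1)))
  er0 <- replicate_error_rate(m, data.frame(sample = "a",
                                            replicate = "a_r"))
  expect_equal(er0$rate, 0)
  expect_error(replicate_error_rate(m, data.frame(sample = character(),
                                                  replicate = character())),
               "no replicate pairs")
})

test_that("half-missing loci never count as mismatches but stay in the denominator", {
  m <- marker_matrix(rbind(a = c(1, 0, NA, 1), b = c(0, 0, 1, NA)))
  er <- replicate_error_rate(m, data.frame(sample = "a", replicate = "b"))
  expect_equal(er$n_mismatches, 1)
  expect_equal(er$n_loci, 4)
  expect_equal(er$rate, 1 / 4)
})

test_that("replicate estimator converges on 2e(1-e) for independent scoring error", {
  set.seed(11)
  eps <- 0.02; L <- 294; n_pairs <- 50
  truth <- matrix(rbinom(n_pairs * L, 1, 0.5), n_pairs, L)
  flip <- function(g) abs(g - rbinom(length(g), 1, eps))
  obs <- rbind(t(apply(truth, 1, flip)), t(apply(truth, 1, flip)))
  ids <- c(paste0("s", 1:n_pairs), paste0("s", 1:n_pairs, "_r"))
  m <- marker_matrix(obs, ids)
  er <- replicate_error_rate(m, data.frame(sample = paste0("s", 1:n_pairs),
                                           replicate = paste0("s", 1:n_pairs, "_r")))
  expected <- 2 * eps * (1 - eps)
  mc_sd <- sqrt(expected * (1 - expected) / (n_pairs * L))
  expect_lt(abs(er$rate - expected), 4 * mc_sd)
})

test_that("pairwise mismatch uses pairwise deletion and matches a double loop", {
  # 3 of 10 loci differ -> 0.3
  a <- c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  b <- a; b[c(1, 5, 9)] <- 1 - b[c(1, 5, 9)]
  m <- marker_matrix(rbind(a = a, b = b))
  expect_equal(pairwise_mismatch(m)$d["a", "b"], 0.3)
  # 2 jointly missing, 1 difference among remaining 8 -> 0.125
  a2 <- c(1, 1, 1, 0, 0, 0, 1, 0, NA, 1)
  b2 <- c(0, 1, 1, 0, 0, 0, 1, 0, 1, NA)
  m2 <- marker_matrix(rbind(a = a2, b = b2))
  expect_equal(pairwise_mismatch(m2)$d["a", "b"], 0.125)
  # brute-force agreement on random instances with missing data
  for (seed in 1:5) {
    mm <- random_marker(8, 20, p_missing = 0.15, seed = seed)
    expect_equal(pairwise_mismatch(mm)$d, brute_mismatch(mm))
  }
  # identical rows -> 0
  m3 <- marker_matrix(rbind(a = c(1, 0), b = c(1, 0)))
  expect_equal(pairwise_mismatch(m3)$d["a", "b"], 0)
})

test_that("clone calling is single-linkage below the threshold, flagging broken triples", {
  d <- matrix(c(0, 0.01, 0.08,
                0.01, 0, 0.01,
                0.08, 0.01, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  part <- call_clones(structure(list(d = d), class = "mismatch_matrix"),
                      0.0465)
  expect_equal(length(unique(part$assignments$lineage)), 1)
  expect_equal(nrow(part$triples), 1)
  expect_setequal(c(part$triples$a, part$triples$c), c("a", "c"))
  # all distances at or above the threshold -> every sample its own lineage
  d2 <- matrix(0.0465, 3, 3, dimnames = dimnames(d)); diag(d2) <- 0
  part2 <- call_clones(structure(list(d = d2), class = "mismatch_matrix"),
                       0.0465)
  expect_equal(length(unique(part2$assignments$lineage)), 3)
})

test_that("clone partitions are order-invariant and monotone in the threshold", {
  mm <- random_marker(12, 40, seed = 3)
  d <- pairwise_mismatch(mm)
  perm <- sample(rownames(mm))
  mm2 <- marker_matrix(unclass(mm)[perm, ])
  d2 <- pairwise_mismatch(mm2)
  canon <- function(p) {
    sp <- split(p$assignments$sample_id, p$assignments$lineage)
    unname(sort(vapply(sp, function(s) paste(sort(s), collapse = "|"),
                       character(1))))
  }
  for (thr in c(0.2, 0.4, 0.6))
    expect_equal(canon(call_clones(d, thr)), canon(call_clones(d2, thr)))
  n_lineages <- vapply(seq(0, 1, by = 0.05), function(thr)
    length(unique(call_clones(d, thr)$assignments$lineage)), numeric(1))
  expect_true(all(diff(n_lineages) <= 0))
})

test_that("clonal fractions count members of multi-member lineages per group", {
  # 54 clonal members of 93 samples -> 58.06%
  asg <- data.frame(
    sample_id = paste0("s", 1:93),
    lineage = c(rep(paste0("c", 1:27), each = 2), paste0("u", 1:39)))
  sf <- sample_frame(data.frame(sample_id = asg$sample_id,
                                population = "P", area = "introduced"))
  cs <- clonal_stats(clone_partition(asg), sf)
  expect_equal(round(100 * cs$clonal_fraction[cs$level == "all"], 2), 58.06)
  # lineage spanning two populations: counted once globally, members in each
  asg2 <- data.frame(sample_id = c("x1", "x2", "y1", "y2"),
                     lineage = c("c1", "c1", "c1", "u1"))
  sf2 <- sample_frame(data.frame(sample_id = asg2$sample_id,
                                 population = c("X", "X", "Y", "Y")))
  cs2 <- clonal_stats(clone_partition(asg2), sf2)
  pop_rows <- cs2[cs2$level == "population", ]
  expect_equal(pop_rows$n_clonal[pop_rows$group == "X"], 2)
  expect_equal(pop_rows$n_clonal[pop_rows$group == "Y"], 1)
  expect_equal(cs2$n_lineages[cs2$level == "all"], 2)
  # all singletons -> clonal fraction zero everywhere
  asg3 <- data.frame(sample_id = c("a", "b"), lineage = c("u1", "u2"))
  sf3 <- sample_frame(data.frame(sample_id = c("a", "b"),
                                 population = c("P", "Q")))
  cs3 <- clonal_stats(clone_partition(asg3), sf3)
  expect_true(all(cs3$clonal_fraction == 0))
  expect_error(clonal_stats(clone_partition(asg3),
                            sample_frame(data.frame(sample_id = "a",
                                                    population = "P"))),
               "missing")
})
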