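test_that("identical config and seed give bit-identical output", {
  cfg <- default_scenario()
  a <- simulate_dataset(cfg, seed = 9)
  b <- simulate_dataset(cfg, seed = 9)
  expect_identical(unclass(a$marker), unclass(b$marker))
  expect_identical(a$crosses, b$crosses)
  expect_identical(a$traits$seeds, b$traits$seeds)
  expect_identical(a$truth$samples, b$truth$samples)
  c_ <- simulate_dataset(cfg, seed = 10)
  expect_false(identical(unclass(a$marker), unclass(c_$marker)))
})

test_that("the default scenario emits the study-scale design", {
  cfg <- default_scenario()
  sim <- simulate_dataset(cfg, seed = 1)
  prim <- drop_replicates(sim$marker, sim$samples)
  expect_equal(dim(prim), c(108, 294))
  expect_equal(nrow(sim$marker), 117)       # 9 replicate rows on top
  expect_equal(sum(!is.na(sim$samples$replicate_of)), 9)
  expect_equal(length(unique(na.omit(
    cfg$populations$crossing_group))), 5)
  # planted introduced clonal fraction: 54 of 93
  tr <- sim$truth$samples
  intro <- tr[tr$population %in%
                cfg$populations$population[cfg$populations$area ==
                                             "introduced"], ]
  sizes <- table(tr$lineage)
  clonal <- sum(intro$lineage %in% names(sizes)[sizes >= 2])
  expect_equal(clonal / nrow(intro), 54 / 93)
  # one planted lineage spans 8 populations
  span <- tapply(tr$population, tr$lineage,
                 function(p) length(unique(p)))
  expect_equal(max(span), 8)
})

test_that("without mutation or scoring error lineages are exact row duplicates", {
  cfg <- default_scenario()
  cfg$rates$mu <- 0; cfg$rates$epsilon <- 0; cfg$rates$epsilon_rep <- 0
  sim <- simulate_dataset(cfg, seed = 5)
  er <- replicate_error_rate(sim$marker, sim$samples)
  expect_equal(er$rate, 0)
  m <- unclass(drop_replicates(sim$marker, sim$samples))
  tr <- sim$truth$samples
  for (lin in c("c1", "c3")) {
    rows <- m[tr$sample_id[tr$lineage == lin], , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # clone caller with any positive threshold recovers lineages perfectly
  mism <- pairwise_mismatch(marker_matrix(m))
  cl <- call_clones(mism, 1e-6)
  got <- setNames(cl$assignments$lineage, cl$assignments$sample_id)
  truth <- setNames(tr$lineage, tr$sample_id)
  expect_equal(mclust::adjustedRandIndex(got[names(truth)], truth), 1)
})

test_that("replicate mismatch matches the closed-form 2e(1-e) expectation", {
  cfg <- default_scenario()
  cfg$rates$mu <- 0
  cfg$rates$epsilon <- 0.0237
  cfg$rates$epsilon_rep <- 0.0237
  cfg$n_replicate_pairs <- 50
  sim <- simulate_dataset(cfg, seed = 7)
  er <- replicate_error_rate(sim$marker, sim$samples)
  expected <- 2 * 0.0237 * (1 - 0.0237)    # 0.0463
  mc_sd <- sqrt(expected * (1 - expected) / (50 * 294))
  expect_lt(abs(er$rate - expected), 4 * mc_sd)
})

test_that("a shared founder lineage reproduces the multi-population clone pattern", {
  cfg <- default_scenario()
  sim <- simulate_dataset(cfg, seed = 4)
  er <- replicate_error_rate(sim$marker, sim$samples)
  prim <- drop_replicates(sim$marker, sim$samples)
  cl <- call_clones(pairwise_mismatch(prim), er)
  asg <- cl$assignments
  pop <- sub("_\\d+$", "", asg$sample_id)
  span <- tapply(pop, asg$lineage, function(p) length(unique(p)))
  sizes <- table(asg$lineage)
  expect_gte(max(span[names(sizes)[sizes >= 2]]), 7)
})

test_that("infeasible configurations are rejected", {
  cfg <- default_scenario()
  cfg$populations$crossing_group[cfg$populations$area == "introduced"] <-
    paste0("g", 1:20)
  expect_error(sim_config(cfg$populations, cfg$composition, cfg$loci,
                          rates = list(), n_s_alleles = 4),
               "more crossing groups")
  comp <- cfg$composition
  comp$n[1] <- 99
  expect_error(sim_config(cfg$populations, comp, cfg$loci, rates = list()),
               "exceeds n_samples")
})

test_that("turning the ratchet off abolishes the planted trait-diversity correlations", {
  cfg <- default_scenario()
  cfg$traits$pollen_decay <- 0
  cfg$traits$mutant_slope <- 0
  cfg$traits$seed_decay <- 0
  cfg$traits$viab_slope <- 0
  cfg$traits$germ_slope <- 0
  null_pairs <- c("pollen~frag_polymorphic", "pollen~hj",
                  "pollen~clonal_fraction", "mutant_fraction~pollen")
  n_runs <- 20
  frac_null <- numeric(0)
  for (s in seq_len(n_runs)) {
    sim <- simulate_dataset(cfg, seed = 100 + s)
    rep <- run_full_analysis(sim$marker, sim$samples, crosses = NULL,
                             traits = sim$traits, n_perm = 99,
                             seed = s, n_boot = 0)
    co <- rep$correlations
    key <- paste(co$var_x, co$var_y, sep = "~")
    p <- co$p_value[match(null_pairs, key)]
    frac_null <- c(frac_null, mean(p > 0.05, na.rm = TRUE))
  }
  # across runs and planted pairs, >= 90% of the tests are null
  expect_gte(mean(frac_null), 0.9)
})
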