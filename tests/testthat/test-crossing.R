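test_that("pair outcomes pool directions and require seeds for compatibility", {
  df <- cross_table(data.frame(
    mother_population = c("A", "B", "C", "C"),
    father_population = c("B", "A", "D", "D"),
    n_flowers = c(3, 2, 5, 4), n_capsules = c(1, 0, 2, 1),
    n_seeds = c(0, 4, 0, 0)))
  oc <- classify_crosses(df)
  # reciprocal A-B records pooled: 4 seeds -> compatible
  expect_equal(oc$outcome[oc$pop_a == "A" & oc$pop_b == "B"], "compatible")
  # capsules without seeds do not confer compatibility
  expect_equal(oc$outcome[oc$pop_a == "C" & oc$pop_b == "D"],
               "incompatible")
  expect_equal(oc$n_flowers[oc$pop_a == "C" & oc$pop_b == "D"], 9)
  # no records -> empty classification; min_flowers gate
  expect_equal(nrow(classify_crosses(cross_table(df[0, ]))), 0)
  oc5 <- classify_crosses(df, min_flowers = 10)
  expect_equal(oc5$outcome[oc5$pop_a == "C" & oc5$pop_b == "D"], "untested")
  # direction-specific reporting is available
  ocd <- classify_crosses(df, pool_directions = FALSE)
  expect_equal(nrow(ocd[ocd$pop_a == "A" & ocd$pop_b == "B", ]), 2)
})

test_that("the study-structure crossing graph yields 5 groups of sizes 13/3/1/1/1", {
  cg <- infer_crossing_groups(figure2_crosses(),
                              populations = all_introduced_pops())
  expect_equal(unname(sort(as.integer(cg$sizes), decreasing = TRUE)),
               c(13, 3, 1, 1, 1))
  mem <- setNames(cg$membership$group, cg$membership$population)
  expect_equal(unname(mem["Gss"]), "unknown")
  expect_equal(length(unique(mem[c("Kt", "Bz", "Re", "Hw", "Bl", "U", "Wi",
                                   "Il", "Gue", "Bg", "Zi", "We", "A")])), 1)
  expect_equal(length(unique(mem[c("Tp", "Tb", "Pl")])), 1)
  expect_false(mem[["Tl"]] %in% mem[c("Kt", "Tp", "Mue", "Mt")])
  expect_true("Pl" %in% cg$self_incompatible)
  expect_equal(nrow(cg$conflicts), 0)
})

test_that("without incompatible crossings every tested population stands alone", {
  df <- cross_table(data.frame(
    mother_population = c("A", "B"), father_population = c("B", "C"),
    n_flowers = c(3, 3), n_capsules = c(2, 2), n_seeds = c(5, 6)))
  cg <- infer_crossing_groups(df)
  expect_equal(length(cg$sizes), 3)
  expect_true(all(cg$sizes == 1))
})

test_that("compatible pairs inside one component are reported as conflicts", {
  df <- cross_table(data.frame(
    mother_population = c("A", "B", "A"),
    father_population = c("B", "C", "C"),
    n_flowers = c(3, 3, 3), n_capsules = c(0, 0, 1),
    n_seeds = c(0, 0, 7)))
  cg <- infer_crossing_groups(df)
  expect_equal(length(cg$sizes), 1)       # A-B-C one component
  expect_equal(nrow(cg$conflicts), 1)
  expect_setequal(c(cg$conflicts$pop_a, cg$conflicts$pop_b), c("A", "C"))
  # removing the compatible edge never changes the partition
  cg2 <- infer_crossing_groups(cross_table(df[1:2, ]))
  expect_equal(cg$membership[cg$membership$population %in% c("A", "B", "C"), ],
               cg2$membership)
})

test_that("inference is order-invariant and idempotent", {
  df <- figure2_crosses()
  perm <- df[sample(nrow(df)), ]
  cg1 <- infer_crossing_groups(df, populations = all_introduced_pops())
  cg2 <- infer_crossing_groups(cross_table(perm),
                               populations = all_introduced_pops())
  expect_equal(cg1$membership, cg2$membership)
  cg3 <- infer_crossing_groups(df, populations = all_introduced_pops())
  expect_equal(cg1$membership, cg3$membership)
})

test_that("recovered groups equal planted S-genotype classes on simulator output", {
  cfg <- default_scenario()
  for (s in 1:2) {
    sim <- simulate_dataset(cfg, seed = s)
    intro <- cfg$populations$population[cfg$populations$area == "introduced"]
    cg <- infer_crossing_groups(sim$crosses, populations = intro)
    mem <- setNames(cg$membership$group, cg$membership$population)
    truth <- setNames(cfg$populations$crossing_group,
                      cfg$populations$population)
    grouped <- names(mem)[mem != "unknown"]
    tab <- table(mem[grouped], truth[grouped])
    # one-to-one correspondence between inferred and planted classes
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) <= 1))
    expect_equal(unname(mem["Gss"]), "unknown")
  }
})

test_that("mate availability counts between-group population pairs", {
  cg <- infer_crossing_groups(figure2_crosses(),
                              populations = all_introduced_pops())
  # groups 13/3/1/1/1 over 19 populations: (171 - 78 - 3) / 171
  expect_equal(mate_availability(cg), (171 - 78 - 3) / 171)
  one <- infer_crossing_groups(cross_table(data.frame(
    mother_population = "A", father_population = "B", n_flowers = 3,
    n_capsules = 0, n_seeds = 0)))
  expect_equal(mate_availability(one), 0)
  all_single <- infer_crossing_groups(cross_table(data.frame(
    mother_population = c("A", "B"), father_population = c("B", "C"),
    n_flowers = 3, n_capsules = 1, n_seeds = 5)))
  expect_equal(mate_availability(all_single), 1)
})
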