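#' Configuration for the clonal-colonization simulator
#'
#' Assembles and validates the full parameterization of a forward
#' simulation of self-incompatible clonal colonization: founder
#' introductions with divergent band profiles, populations propagated
#' clonally with somatic band flips, per-scoring error, replicate
#' re-scorings, S-genotype-driven crossing outcomes, and a latent
#' mutation-load counter that degrades reproductive traits (the ratchet).
#'
#' @param populations data.frame: `population`, `area`
#'   (`native`/`introduced`), `region`, `crossing_group` (true S class),
#'   `introduction` (founder event id, `NA` for native), `n_samples`,
#'   `clonal_generations` (propagation depth), `flowering` (logical),
#'   `latitude`, `longitude`.
#' @param composition data.frame `population`, `lineage`, `n`: how many of
#'   a population's samples belong to each planted clonal lineage; samples
#'   not covered are independent (singleton) genets.
#' @param loci list of locus-class definitions (see [default_scenario()]
#'   for the shape): counts and frequency ranges for fixed, area-specific,
#'   shared and introduced-pool fragments.
#' @param rates list: `mu` (somatic flip / locus / generation), `epsilon`
#'   (scoring flip / locus / scoring), `epsilon_rep` (replicate
#'   re-extraction + scoring flip rate), `delta` (divergence flip rate
#'   between genets of one introduction, at variable loci).
#' @param n_replicate_pairs number of replicate re-scorings.
#' @param n_s_alleles size of the S-allele pool.
#' @param traits list of trait-model parameters (baseline pollen, decay
#'   per load unit, mutant-flower logistic intercept/slope on load, seed
#'   and viability parameters, `load_rate` Poisson load per generation).
#' @param crossing list: flowers per cross, seed/capsule distributions,
#'   intra-population test settings.
#' @param seed master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(populations, composition, loci, rates,
                       n_replicate_pairs = 9, n_s_alleles = 8,
                       traits = list(), crossing = list(), seed = 1L) {
  rates <- utils::modifyList(list(mu = 1e-4, epsilon = 0.01,
                                  epsilon_rep = 0.037, delta = 0.06), rates)
  for (r in c("mu", "epsilon", "epsilon_rep", "delta"))
    stopifnot(rates[[r]] >= 0, rates[[r]] <= 1)
  traits <- utils::modifyList(list(
    flowers_per_pop = 40, capsules_per_pop = 15, dilution = 1000,
    pollen_baseline = 8000, pollen_decay = 0.05,
    ovule_mean = 10, mutant_intercept = -3, mutant_slope = 0.3,
    seed_mean = 8, seed_decay = 0.03,
    width_base = 0.60, width_decay = 0.008, width_sd = 0.04,
    viab_intercept = 2.2, viab_slope = 0.25, dead_share = 0.6,
    germ_intercept = 2.2, germ_slope = 0.2, load_rate = 0.15), traits)
  crossing <- utils::modifyList(list(
    flowers_per_cross = 5, seed_lambda = 12, capsule_p = 0.2,
    between_per_pop = 2, intra_population = NULL, intra_flowers = 41),
    crossing)
  stopifnot(is.data.frame(populations), is.data.frame(composition))
  agg <- tapply(composition$n, composition$population, sum)
  over <- names(agg)[agg > populations$n_samples[
    match(names(agg), populations$population)]]
  if (length(over) > 0)
    stop("lineage composition exceeds n_samples in: ",
         paste(over, collapse = ", "))
  n_groups <- length(unique(stats::na.omit(populations$crossing_group)))
  if (n_groups > choose(n_s_alleles, 2))
    stop("more crossing groups than distinct S-genotypes available")
  structure(list(populations = populations, composition = composition,
                 loci = loci, rates = rates,
                 n_replicate_pairs = n_replicate_pairs,
                 n_s_alleles = n_s_alleles, traits = traits,
                 crossing = crossing, seed = seed),
            class = "sim_config")
}

#' Default colonization scenario at the scale of the motivating study
#'
#' 20 introduced populations on a ~150 km transect (93 samples) plus 3
#' native populations (15 samples), 294 loci, 9 replicate pairs; five
#' planted crossing groups of sizes 13/3/1/1/1 with one population
#' (`Gss`) never flowering; 10 planted clonal lineages holding 54 of the
#' 93 introduced samples, one of them (`c1`) spanning 8 populations.
#' Scoring error and replicate re-extraction error are set so the expected
#' replicate mismatch rate is ~4.6%.
#'
#' @param seed master seed (default 1).
#' @return a [sim_config()].
#' @export
default_scenario <- function(seed = 1L) {
  intro <- data.frame(
    population = c("Tp", "Tb", "Tl", "Kt", "Pl", "Bz", "Re", "Hw", "Mue",
                   "Mt", "Bl", "U", "Wi", "Il", "Gue", "Bg", "Zi", "Gss",
                   "We", "A"),
    area = "introduced", region = "transect",
    crossing_group = c("blue", "blue", "red", "green", "blue", "green",
                       "green", "green", "pink", "violet", "green", "green",
                       "green", "green", "green", "green", "green", "green",
                       "green", "green"),
    introduction = c("I1", "I1", "I1", "I1", "I2", "I2", "I2", "I2", "I3",
                     "I3", "I3", "I4", "I4", "I4", "I4", "I5", "I5", "I5",
                     "I6", "I6"),
    n_samples = c(3, 9, 3, 3, 7, 4, 5, 5, 3, 3, 4, 5, 10, 4, 4, 4, 3, 6,
                  4, 4),
    flowering = TRUE,
    latitude = 48.52, longitude = seq(9.05, 10.95, length.out = 20),
    stringsAsFactors = FALSE)
  intro$flowering[intro$population == "Gss"] <- FALSE
  nat <- data.frame(
    population = c("UzT", "Kz9", "Bk10"),
    area = "native",
    region = c("Turkey-Eastern", "Georgia-Northern", "Georgia-Central"),
    crossing_group = NA_character_, introduction = NA_character_,
    n_samples = c(4, 5, 6), flowering = TRUE,
    latitude = c(40.62, 42.66, 41.75),
    longitude = c(40.29, 44.62, 43.48), stringsAsFactors = FALSE)
  populations <- rbind(intro, nat)
  clonal <- c(Tp = 2, Tb = 4, Kt = 2, Pl = 6, Bz = 4, Re = 5, Hw = 5,
              Bl = 3, U = 3, Wi = 8, Il = 2, Gue = 1, Bg = 2, Zi = 3,
              Gss = 4)
  frac <- clonal[populations$population] / populations$n_samples
  frac[is.na(frac)] <- 0
  populations$clonal_generations <-
    ifelse(populations$area == "native", 0L, 5L + round(45 * frac))
  composition <- data.frame(
    population = c("Re", "Wi", "Bz", "Bl", "U", "Il", "Gue", "Bg",
                   "Tb", "Pl", "Hw", "Zi", "Gss", "Tp", "Wi", "Bz", "Kt"),
    lineage = c(rep("c1", 8),
                "c2", "c3", "c4", "c5", "c6", "c7", "c8", "c9", "c10"),
    n = c(5, 4, 2, 3, 3, 2, 1, 2, 4, 6, 5, 3, 4, 2, 4, 2, 2),
    stringsAsFactors = FALSE)
  loci <- list(
    fixed = list(n = 4),
    native_rare = list(n = 40, freq = c(0.03, 0.13)),
    native_common = list(n = 5, freq = c(0.20, 0.50)),
    shared_rare = list(n = 25, freq = c(0.03, 0.13), carry = c(0, 0.10)),
    shared_common = list(n = 96, freq = c(0.15, 0.85)),
    introduced = list(n = 124, carry = c(0.08, 0.45)))
  sim_config(populations, composition, loci, rates = list(),
             crossing = list(intra_population = "Pl"), seed = seed)
}

sim_n_loci <- function(loci) sum(vapply(loci, `[[`, numeric(1), "n"))

# per-locus class table: class, p_nat draw range, carry (introduction
# profile) rule, whether genet-divergence flips apply
sim_locus_table <- function(loci) {
  data.frame(
    class = rep(names(loci), vapply(loci, `[[`, numeric(1), "n")),
    stringsAsFactors = FALSE)
}

rbern <- function(n, p) stats::rbinom(n, 1L, p)

xor_flip <- function(bits, rate) {
  flips <- rbern(length(bits), rate)
  as.integer(bitwXor(as.integer(bits), flips))
}

#' Simulate a full data set with known ground truth
#'
#' Runs the forward scenario in `config`: draws locus frequencies and
#' introduction band profiles, builds clonal-lineage and singleton genet
#' genotypes, propagates somatic band flips, scores every sample with
#' per-locus error (replicate pairs are independent re-scorings of the
#' same individuals with their own error rate), generates crossing
#' outcomes from the planted S-genotypes (identical unordered S-genotype =
#' no seeds), and draws reproductive traits from the latent mutation load.
#' Identical config and seed give identical output.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list of class `aflp_sim`: `marker` ([marker_matrix()], primary
#'   samples plus replicate rows), `samples` ([sample_frame()]), `crosses`
#'   ([cross_table()]), `traits` ([trait_tables()]), `truth` (list with
#'   per-sample `samples` ground truth: introduction, lineage, load,
#'   S-alleles; and per-population `populations` with the true crossing
#'   group).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  pops <- config$populations
  loci <- config$loci
  rates <- config$rates
  L <- sim_n_loci(loci)
  locus_class <- sim_locus_table(loci)$class
  locus_ids <- paste0("L", seq_len(L))

  # --- per-locus frequency model --------------------------------------
  p_nat <- numeric(L); carry <- numeric(L); eligible <- logical(L)
  for (cl in names(loci)) {
    ix <- which(locus_class == cl)
    spec <- loci[[cl]]
    p_nat[ix] <- switch(cl,
      fixed = 1,
      native_rare = , native_common = , shared_rare = , shared_common =
        stats::runif(length(ix), spec$freq[1], spec$freq[2]),
      introduced = 0)
    carry[ix] <- switch(cl,
      fixed = 1,
      native_rare = , native_common = 0,
      shared_rare = stats::runif(length(ix), spec$carry[1], spec$carry[2]),
      shared_common = p_nat[ix],
      introduced = stats::runif(length(ix), spec$carry[1], spec$carry[2]))
    eligible[ix] <- cl %in% c("shared_common", "introduced")
  }

  # --- introduction profiles and genet genotypes ----------------------
  intro_ids <- sort(unique(stats::na.omit(pops$introduction)))
  profiles <- t(vapply(intro_ids, function(i) rbern(L, carry),
                       integer(L)))
  rownames(profiles) <- intro_ids
  genet_from <- function(intro) {
    g <- profiles[intro, ]
    g[eligible] <- xor_flip(g[eligible], rates$delta)
    g
  }
  lineages <- unique(config$composition$lineage)
  lin_intro <- vapply(lineages, function(l) {
    p <- config$composition$population[config$composition$lineage == l][1]
    pops$introduction[pops$population == p]
  }, character(1))
  lin_geno <- t(vapply(lineages, function(l) genet_from(lin_intro[l]),
                       integer(L)))
  rownames(lin_geno) <- lineages

  # --- samples --------------------------------------------------------
  samp <- list(); truth <- list(); G <- list()
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]
    n <- pops$n_samples[pi]
    gen_p <- pops$clonal_generations[pi]
    comp <- config$composition[config$composition$population == pop, ,
                               drop = FALSE]
    lin_of <- rep(NA_character_, n)
    k <- 0
    for (r in seq_len(nrow(comp))) {
      lin_of[k + seq_len(comp$n[r])] <- comp$lineage[r]
      k <- k + comp$n[r]
    }
    ids <- sprintf("%s_%d", pop, seq_len(n))
    for (s in seq_len(n)) {
      gens <- if (gen_p > 0) sample.int(gen_p, 1) else 0L
      load <- stats::rpois(1, config$traits$load_rate * gens + 0.2)
      if (pops$area[pi] == "native") {
        g <- rbern(L, p_nat)
        lin <- paste0("u_", ids[s])
      } else if (!is.na(lin_of[s])) {
        g <- xor_flip(lin_geno[lin_of[s], ], 1 - (1 - rates$mu)^gens)
        lin <- lin_of[s]
      } else {
        g0 <- genet_from(pops$introduction[pi])
        g <- xor_flip(g0, 1 - (1 - rates$mu)^gens)
        lin <- paste0("u_", ids[s])
      }
      G[[ids[s]]] <- g
      truth[[ids[s]]] <- data.frame(
        sample_id = ids[s], population = pop,
        introduction = pops$introduction[pi], lineage = lin,
        generations = gens, load = load, stringsAsFactors = FALSE)
    }
  }
  truth_s <- do.call(rbind, truth)
  rownames(truth_s) <- NULL
  Gm <- do.call(rbind, G)
  X <- Gm
  flips <- matrix(rbern(length(X), rates$epsilon), nrow(X))
  X <- abs(X - flips)

  # --- replicate re-scorings ------------------------------------------
  introduced_ids <- truth_s$sample_id[truth_s$population %in%
                                        pops$population[pops$area == "introduced"]]
  rep_of <- sample(introduced_ids, config$n_replicate_pairs)
  rep_ids <- paste0(rep_of, "_r")
  R <- t(vapply(rep_of, function(id)
    xor_flip(Gm[id, ], rates$epsilon_rep), integer(L)))
  rownames(R) <- rep_ids
  X <- rbind(X, R)
  mm <- marker_matrix(X, rownames(X), locus_ids)

  # --- sample frame ----------------------------------------------------
  pidx <- match(truth_s$population, pops$population)
  cluster <- ifelse(is.na(pops$introduction[pidx]),
                    paste0("N_", pops$region[pidx]),
                    pops$introduction[pidx])
  samples <- data.frame(
    sample_id = truth_s$sample_id, population = truth_s$population,
    region = pops$region[pidx], area = pops$area[pidx],
    latitude = pops$latitude[pidx], longitude = pops$longitude[pidx],
    replicate_of = NA_character_, external_cluster = cluster,
    stringsAsFactors = FALSE)
  rep_rows <- samples[match(rep_of, samples$sample_id), ]
  rep_rows$sample_id <- rep_ids
  rep_rows$replicate_of <- rep_of
  samples <- sample_frame(rbind(samples, rep_rows))

  # --- S-genotypes and crossing outcomes ------------------------------
  groups <- sort(unique(stats::na.omit(pops$crossing_group)))
  s_pairs <- t(utils::combn(config$n_s_alleles, 2))[seq_along(groups), ,
                                                    drop = FALSE]
  rownames(s_pairs) <- groups
  crosses <- sim_crosses(config, s_pairs)

  # --- traits ----------------------------------------------------------
  traits <- sim_traits(config, truth_s)

  grp_of_sample <- pops$crossing_group[pidx]
  gi <- match(grp_of_sample, rownames(s_pairs))
  truth_s$s1 <- s_pairs[, 1][gi]
  truth_s$s2 <- s_pairs[, 2][gi]
  truth_pop <- pops[, c("population", "area", "crossing_group",
                        "introduction", "clonal_generations")]
  structure(list(marker = mm, samples = samples, crosses = crosses,
                 traits = traits,
                 truth = list(samples = truth_s, populations = truth_pop,
                              s_pairs = s_pairs, seed = seed)),
            class = "aflp_sim")
}

sim_crosses <- function(config, s_pairs) {
  pops <- config$populations
  cr <- config$crossing
  flowering <- pops$population[pops$area == "introduced" & pops$flowering]
  grp <- stats::setNames(pops$crossing_group, pops$population)
  rec <- list()
  add <- function(mo, fa, fl, cp, sd_) {
    rec[[length(rec) + 1]] <<- data.frame(
      mother_population = mo, father_population = fa,
      n_flowers = fl, n_capsules = cp, n_seeds = sd_,
      stringsAsFactors = FALSE)
  }
  same_s <- function(a, b) {
    identical(sort(s_pairs[grp[a], ]), sort(s_pairs[grp[b], ]))
  }
  # all pairs within a crossing group: tested, incompatible
  for (g in unique(grp[flowering])) {
    mem <- flowering[grp[flowering] == g]
    if (length(mem) >= 2) {
      prs <- utils::combn(mem, 2)
      for (k in seq_len(ncol(prs))) {
        fl <- 2 + stats::rpois(1, cr$flowers_per_cross - 2)
        add(prs[1, k], prs[2, k], fl, stats::rbinom(1, fl, cr$capsule_p),
            0L)
      }
    }
  }
  # each flowering population crossed with populations of other groups
  for (p in flowering) {
    others <- flowering[grp[flowering] != grp[p]]
    if (length(others) == 0) next
    partners <- sample(others, min(cr$between_per_pop, length(others)))
    for (q in partners) {
      fl <- 2 + stats::rpois(1, cr$flowers_per_cross - 2)
      if (same_s(p, q)) {        # defensive; distinct groups have distinct S
        add(p, q, fl, stats::rbinom(1, fl, cr$capsule_p), 0L)
      } else {
        cp <- max(1L, stats::rbinom(1, fl, 0.7))
        add(p, q, fl, cp, stats::rpois(1, cr$seed_lambda) + 1L)
      }
    }
  }
  if (!is.null(cr$intra_population) &&
      cr$intra_population %in% flowering) {
    add(cr$intra_population, cr$intra_population, cr$intra_flowers,
        0L, 0L)
  }
  cross_table(do.call(rbind, rec))
}

sim_traits <- function(config, truth_s) {
  tp <- config$traits
  pops <- config$populations
  flowers <- list(); capsules <- list(); seeds <- list()
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]
    members <- truth_s[truth_s$population == pop, , drop = FALSE]
    sid <- rep(members$sample_id, length.out = tp$flowers_per_pop)
    load <- members$load[match(sid, members$sample_id)]
    mutant <- rbern(length(sid),
                    stats::plogis(tp$mutant_intercept +
                                    tp$mutant_slope * load))
    subtype <- sample(c("no_filament", "one_stamen", "other"),
                      length(sid), replace = TRUE,
                      prob = c(0.75, 0.2, 0.05))
    pollen_true <- tp$pollen_baseline * (1 - tp$pollen_decay)^load
    ali <- t(vapply(pollen_true, function(m)
      stats::rpois(10, m / tp$dilution), integer(10)))
    colnames(ali) <- paste0("a", 1:10)
    flowers[[pop]] <- data.frame(
      population = pop, sample_id = sid,
      flower_class = ifelse(mutant == 1, subtype, "normal"),
      ali, ovule_count = pmax(1L, stats::rpois(length(sid), tp$ovule_mean)),
      stringsAsFactors = FALSE)
    csid <- rep(members$sample_id, length.out = tp$capsules_per_pop)
    cload <- members$load[match(csid, members$sample_id)]
    cid <- sprintf("%s_cap%d", pop, seq_along(csid))
    nsd <- stats::rpois(length(csid),
                        tp$seed_mean * exp(-tp$seed_decay * cload))
    capsules[[pop]] <- data.frame(
      population = pop, sample_id = csid, capsule_id = cid,
      n_seeds = nsd, stringsAsFactors = FALSE)
    for (ci in seq_along(cid)) {
      if (nsd[ci] == 0) next
      ld <- cload[ci]
      w <- pmax(0.2, stats::rnorm(nsd[ci],
                                  tp$width_base - tp$width_decay * ld,
                                  tp$width_sd))
      pv <- stats::plogis(tp$viab_intercept - tp$viab_slope * ld)
      cls <- sample(c("viable", "abnormal", "dead"), nsd[ci],
                    replace = TRUE,
                    prob = c(pv, (1 - pv) * (1 - tp$dead_share),
                             (1 - pv) * tp$dead_share))
      germ <- rbern(nsd[ci],
                    stats::plogis(tp$germ_intercept - tp$germ_slope * ld))
      seeds[[length(seeds) + 1]] <- data.frame(
        population = pop, capsule_id = cid[ci],
        width = round(w, 3), length = round(w * 1.3, 3),
        viability = cls, germinated = germ, stringsAsFactors = FALSE)
    }
  }
  trait_tables(flowers = do.call(rbind, c(flowers, make.row.names = FALSE)),
               capsules = do.call(rbind, c(capsules,
                                           make.row.names = FALSE)),
               seeds = do.call(rbind, c(seeds, make.row.names = FALSE)))
}

#' @export
print.aflp_sim <- function(x, ...) {
  cat(sprintf("simulated data set: %d samples (%d replicate rows) x %d loci, %d populations\n",
              nrow(x$marker), sum(!is.na(x$samples$replicate_of)),
              ncol(x$marker), length(unique(x$samples$population))))
  invisible(x)
}

#' Write the simulator output tables to a directory
#'
#' @param sim an [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_matrix(sim$marker, file.path(dir, "markers.tsv"))
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = ",", quote = FALSE, row.names = FALSE)
  wr(sim$samples, "samples.csv")
  wr(sim$crosses, "crosses.csv")
  wr(sim$traits$flowers, "flowers.csv")
  wr(sim$traits$capsules, "capsules.csv")
  wr(sim$traits$seeds, "seeds.csv")
  wr(sim$truth$samples, "truth_samples.csv")
  wr(sim$truth$populations, "truth_populations.csv")
  invisible(dir)
}

#' Analytically targeted among-area AMOVA percentage of a configuration
#'
#' The expected among-area percent of variance implied by the generator's
#' frequency model. Sums of squares are linear in the pairwise squared
#' distances, so their expectation is exact given the expected per-pair
#' mismatch counts; those follow in closed form from the locus-class
#' frequency ranges (uniform moments), the introduction/lineage structure
#' of the configuration and the flip rates. Used to validate that a
#' simulated data set recovers the structure the generator encodes.
#'
#' @param config a [sim_config()].
#' @return list: `pct_among`, `phi_st`, and the expected `table`.
#' @export
expected_amova_target <- function(config) {
  pops <- config$populations
  loci <- config$loci
  rates <- config$rates
  eps <- rates$epsilon; del <- rates$delta; mu <- rates$mu
  xor2 <- function(a, b) a * (1 - b) + b * (1 - a)
  e2 <- 2 * eps * (1 - eps)
  umom <- function(rg) {
    if (length(rg) == 1) rg <- c(rg, rg)
    list(m1 = mean(rg), m2 = (rg[1]^2 + rg[1] * rg[2] + rg[2]^2) / 3)
  }
  # class -> moments of p (native freq) and pi (introduction carry prob)
  cls <- list(
    fixed = list(n = loci$fixed$n, p = umom(1), pi = umom(1),
                 elig = FALSE, linked = TRUE),
    native_rare = list(n = loci$native_rare$n,
                       p = umom(loci$native_rare$freq), pi = umom(0),
                       elig = FALSE, linked = FALSE),
    native_common = list(n = loci$native_common$n,
                         p = umom(loci$native_common$freq), pi = umom(0),
                         elig = FALSE, linked = FALSE),
    shared_rare = list(n = loci$shared_rare$n,
                       p = umom(loci$shared_rare$freq),
                       pi = umom(loci$shared_rare$carry),
                       elig = FALSE, linked = FALSE),
    shared_common = list(n = loci$shared_common$n,
                         p = umom(loci$shared_common$freq),
                         pi = umom(loci$shared_common$freq),
                         elig = TRUE, linked = TRUE),
    introduced = list(n = loci$introduced$n, p = umom(0),
                      pi = umom(loci$introduced$carry),
                      elig = TRUE, linked = FALSE))
  # linear maps x -> c0 + c1 * x for observation probabilities
  lin_eps <- function(c0, c1) c(eps + (1 - 2 * eps) * c0,
                                (1 - 2 * eps) * c1)
  lin_del <- function(c0, c1) c(del + (1 - 2 * del) * c0,
                                (1 - 2 * del) * c1)
  m_nn <- 0; m_ii_diff <- 0; m_ni <- 0
  elig_total <- 0; n_loci <- 0
  for (cl in cls) {
    n_loci <- n_loci + cl$n
    if (cl$elig) elig_total <- elig_total + cl$n
    # native observed prob p' = eps + (1-2eps) p
    a <- lin_eps(0, 1)
    Ep1 <- a[1] + a[2] * cl$p$m1
    Ep2 <- a[1]^2 + 2 * a[1] * a[2] * cl$p$m1 + a[2]^2 * cl$p$m2
    m_nn <- m_nn + cl$n * 2 * (Ep1 - Ep2)
    # introduced observed prob t = eps o (delta?) o pi
    b <- if (cl$elig) lin_eps(lin_del(0, 1)[1], lin_del(0, 1)[2]) else
      lin_eps(0, 1)
    Et1 <- b[1] + b[2] * cl$pi$m1
    Et2 <- b[1]^2 + 2 * b[1] * b[2] * cl$pi$m1 + b[2]^2 * cl$pi$m2
    m_ii_diff <- m_ii_diff + cl$n * 2 * (Et1 - Et2)
    # native x introduced: E[p'] + E[t] - 2 E[p' t]
    Ept <- if (cl$linked) {
      a[1] * b[1] + (a[1] * b[2] + a[2] * b[1]) * cl$p$m1 +
        a[2] * b[2] * cl$p$m2
    } else Ep1 * Et1
    m_ni <- m_ni + cl$n * (Ep1 + Et1 - 2 * Ept)
  }
  # same-introduction genet pairs: delta-divergence at eligible loci
  q_del <- xor2(del, del)
  m_ii_same_intro <- elig_total * xor2(q_del, e2) +
    (n_loci - elig_total) * e2
  # same-lineage pairs: somatic divergence only
  gbar <- (pops$clonal_generations + 1) / 2
  m_lineage <- function(g1, g2) {
    q <- xor2(1 - (1 - mu)^g1, 1 - (1 - mu)^g2)
    n_loci * xor2(q, e2)
  }
  # expected squared distance for every primary sample pair
  n <- sum(pops$n_samples)
  area <- rep(pops$area, pops$n_samples)
  pop_of <- rep(pops$population, pops$n_samples)
  intro_of <- rep(pops$introduction, pops$n_samples)
  g_of <- rep(gbar, pops$n_samples)
  lin_of <- rep(NA_character_, n)
  for (r in seq_len(nrow(config$composition))) {
    ix <- which(pop_of == config$composition$population[r] &
                  is.na(lin_of))
    lin_of[ix[seq_len(config$composition$n[r])]] <-
      config$composition$lineage[r]
  }
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- if (area[i] == "native" && area[j] == "native") m_nn
    else if (xor(area[i] == "native", area[j] == "native")) m_ni
    else if (!is.na(lin_of[i]) && identical(lin_of[i], lin_of[j]))
      m_lineage(g_of[i], g_of[j])
    else if (identical(intro_of[i], intro_of[j])) m_ii_same_intro
    else m_ii_diff
    d2[i, j] <- d2[j, i] <- m
  }
  rownames(d2) <- colnames(d2) <- paste0("v", seq_len(n))
  fit <- amova_fit(d2, data.frame(g1 = area, row.names = rownames(d2),
                                  stringsAsFactors = FALSE))
  list(pct_among = fit$table$pct_variance[1],
       phi_st = unname(fit$phi["phi_ST"]), table = fit$table)
}
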