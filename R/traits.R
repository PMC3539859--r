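#' Androecium-mutant flower frequency per population
#'
#' Fraction of mutant flowers per population, with an optional rank-test
#' comparison of the per-population fractions between native and introduced
#' areas (Mann-Whitney U).
#'
#' @param counts data.frame with `population`, `n_mutant`, `n_flowers`; or
#'   a flowers trait table (with `flower_class`, where any class other than
#'   `"normal"` counts as mutant), from which counts are tallied.
#' @param areas optional named vector population -> area, or a
#'   [sample_frame()] (the population's area is taken from its samples).
#' @return list: `per_population` (counts and `fraction`), and `area_test`
#'   (data.frame with U and p, `NULL` without area info).
#' @export
mutant_flower_frequency <- function(counts, areas = NULL) {
  if (!is.null(counts$flower_class)) {
    tot <- table(counts$population)
    mut <- tapply(counts$flower_class != "normal", counts$population, sum)
    counts <- data.frame(population = names(tot),
                         n_mutant = as.integer(mut[names(tot)]),
                         n_flowers = as.integer(tot),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("population", "n_mutant", "n_flowers") %in% names(counts)))
  if (any(counts$n_flowers < 1)) stop("n_flowers must be >= 1")
  if (any(counts$n_mutant > counts$n_flowers))
    stop("more mutant than observed flowers in population(s): ",
         paste(counts$population[counts$n_mutant > counts$n_flowers],
               collapse = ", "))
  counts$fraction <- counts$n_mutant / counts$n_flowers
  area_test <- NULL
  if (!is.null(areas)) {
    pa <- population_area(areas)
    av <- pa[counts$population]
    if (length(unique(stats::na.omit(av))) == 2) {
      lv <- sort(unique(stats::na.omit(av)))
      w <- stats::wilcox.test(counts$fraction[av == lv[1]],
                              counts$fraction[av == lv[2]],
                              exact = FALSE, correct = FALSE)
      area_test <- data.frame(test = "mann_whitney_u",
                              groups = paste(lv, collapse = " vs "),
                              statistic = unname(w$statistic),
                              p_value = w$p.value, stringsAsFactors = FALSE)
    }
  }
  list(per_population = counts, area_test = area_test)
}

population_area <- function(areas) {
  if (is.data.frame(areas)) {
    stopifnot(all(c("population", "area") %in% names(areas)))
    tab <- unique(areas[, c("population", "area")])
    stats::setNames(tab$area, tab$population)
  } else {
    areas
  }
}

#' Total pollen per flower from aliquot counts
#'
#' Pollen suspensions are counted in 10 aliquots per flower; the per-flower
#' total is the aliquot mean multiplied by the dilution factor.
#'
#' @param aliquots numeric vector of exactly 10 counts, or an n x 10 matrix
#'   (one flower per row).
#' @param dilution dilution factor (default 1000).
#' @return grains per flower (scalar or vector).
#' @examples
#' pollen_total(rep(5, 10))        # 5000
#' pollen_total(1:10)              # 5500
#' @export
pollen_total <- function(aliquots, dilution = 1000) {
  if (is.matrix(aliquots) || is.data.frame(aliquots)) {
    aliquots <- as.matrix(aliquots)
    if (ncol(aliquots) != 10)
      stop("expected 10 aliquot counts per flower, got ", ncol(aliquots))
    if (any(aliquots < 0, na.rm = TRUE)) stop("negative aliquot count")
    return(rowMeans(aliquots) * dilution)
  }
  if (length(aliquots) != 10)
    stop("expected 10 aliquot counts, got ", length(aliquots))
  if (any(aliquots < 0)) stop("negative aliquot count")
  mean(aliquots) * dilution
}

#' Pollen/ovule ratio
#'
#' Total pollen grains per flower divided by the ovule count of the same
#' flower; a classic index of mating-system investment.
#'
#' @param pollen grains per flower.
#' @param ovules ovule count (>= 1).
#' @return ratio (vectorised).
#' @export
pollen_ovule_ratio <- function(pollen, ovules) {
  if (any(ovules < 1)) stop("ovule count must be >= 1")
  pollen / ovules
}

#' Per-group seed summaries
#'
#' Per group: seed number per capsule, per-capsule mean seed width (the
#' size unit of analysis), viability-class fractions and germination
#' fraction, each with its count provenance; plus rank-test comparisons of
#' seeds per capsule and capsule mean width across groups.
#'
#' @param traits a [trait_tables()] list (`capsules` and/or `seeds` used).
#' @param by grouping column present in the tables (default
#'   `"population"`).
#' @return list: `summary` (one row per group), `capsule_widths`
#'   (per-capsule mean widths with group), `tests` (group comparisons).
#' @export
seed_summaries <- function(traits, by = "population") {
  caps <- traits$capsules
  seeds <- traits$seeds
  groups <- sort(unique(c(if (!is.null(caps)) caps[[by]],
                          if (!is.null(seeds)) seeds[[by]])))
  cw <- NULL
  if (!is.null(seeds) && !is.null(seeds$width)) {
    cw <- stats::aggregate(seeds["width"],
                           by = list(group = seeds[[by]],
                                     capsule_id = seeds$capsule_id),
                           FUN = mean, na.rm = TRUE)
    names(cw)[3] <- "mean_width"
  }
  rows <- lapply(groups, function(g) {
    n_caps <- if (!is.null(caps)) sum(caps[[by]] == g) else 0L
    seed_per_cap <- if (n_caps > 0)
      mean(caps$n_seeds[caps[[by]] == g]) else NA_real_
    gw <- if (!is.null(cw)) cw$mean_width[cw$group == g] else numeric(0)
    sg <- if (!is.null(seeds)) seeds[seeds[[by]] == g, , drop = FALSE] else NULL
    viab <- function(cl) {
      if (is.null(sg) || is.null(sg$viability)) return(NA_real_)
      tested <- sum(!is.na(sg$viability))
      if (tested == 0) return(NA_real_)
      sum(sg$viability == cl, na.rm = TRUE) / tested
    }
    germ <- if (!is.null(sg) && !is.null(sg$germinated) &&
                sum(!is.na(sg$germinated)) > 0)
      mean(sg$germinated, na.rm = TRUE) else NA_real_
    data.frame(group = g, n_capsules = n_caps,
               seeds_per_capsule = seed_per_cap,
               mean_capsule_width = if (length(gw) > 0) mean(gw) else NA_real_,
               n_seeds_measured = if (is.null(sg)) 0L else nrow(sg),
               frac_viable = viab("viable"), frac_abnormal = viab("abnormal"),
               frac_dead = viab("dead"), frac_germinated = germ,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  tests <- NULL
  add_test <- function(values, grouping, label) {
    grouping <- factor(grouping)
    if (nlevels(grouping) < 2 || length(values) < 3) return(NULL)
    if (nlevels(grouping) == 2) {
      w <- stats::wilcox.test(values ~ grouping, exact = FALSE,
                              correct = FALSE)
      data.frame(variable = label, test = "mann_whitney_u",
                 statistic = unname(w$statistic), p_value = w$p.value,
                 stringsAsFactors = FALSE)
    } else {
      k <- stats::kruskal.test(values, grouping)
      data.frame(variable = label, test = "kruskal_wallis_h",
                 statistic = unname(k$statistic), p_value = k$p.value,
                 stringsAsFactors = FALSE)
    }
  }
  if (!is.null(caps))
    tests <- rbind(tests, add_test(caps$n_seeds, caps[[by]],
                                   "seeds_per_capsule"))
  if (!is.null(cw))
    tests <- rbind(tests, add_test(cw$mean_width, cw$group,
                                   "capsule_mean_width"))
  list(summary = summary, capsule_widths = cw, tests = tests)
}
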