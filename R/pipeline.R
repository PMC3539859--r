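#' Run the full dominant-marker analysis pipeline
#'
#' One call from raw tables to a run summary: estimates the replicate
#' error rate, calls clonal lineages, computes diversity tables per
#' population and per area, runs PCoA on Nei & Li distances with an
#' area rank test, AMOVA by area and by population within the introduced
#' area, infers crossing groups and mate availability, summarises traits,
#' and computes the trait-diversity correlation suite plus the
#' genetic-geographic Mantel correlation.
#'
#' @param marker a [marker_matrix()] (may include replicate rows).
#' @param samples a [sample_frame()].
#' @param crosses a [cross_table()] or `NULL`.
#' @param traits a [trait_tables()] list or `NULL`.
#' @param n_perm permutations for AMOVA/Mantel tests.
#' @param seed integer seed for every stochastic step.
#' @param n_boot bootstrap replicates for gene diversity.
#' @return list of class `aflp_report` with elements `error_rate`,
#'   `clones`, `clonal_stats`, `diversity_population`, `diversity_area`,
#'   `pcoa`, `pcoa_area_test`, `amova_area`, `amova_population`,
#'   `crossing`, `mate_availability`, `traits`, `correlations`,
#'   `geo_genetic`.
#' @export
run_full_analysis <- function(marker, samples, crosses = NULL,
                              traits = NULL, n_perm = 999, seed = 1L,
                              n_boot = 200) {
  out <- list()
  has_reps <- !is.null(samples$replicate_of) &&
    any(!is.na(samples$replicate_of))
  if (has_reps) {
    out$error_rate <- replicate_error_rate(marker, samples)
    primary <- drop_replicates(marker, samples)
  } else {
    out$error_rate <- NULL
    primary <- marker
  }
  psamples <- samples[samples$sample_id %in% rownames(primary), ,
                      drop = FALSE]
  if (!is.null(out$error_rate)) {
    mism <- pairwise_mismatch(primary)
    out$clones <- call_clones(mism, out$error_rate)
    out$clonal_stats <- clonal_stats(out$clones, psamples)
  }
  out$diversity_population <- diversity_table(primary, psamples,
                                              by = "population",
                                              n_boot = n_boot, seed = seed)
  if (!is.null(psamples$area)) {
    out$diversity_area <- diversity_table(primary, psamples, by = "area",
                                          n_boot = n_boot, seed = seed)
    d <- nei_li_dist(primary)
    if (!anyNA(d)) {
      out$pcoa <- band_pcoa(d)
      out$pcoa_area_test <- axis_group_test(out$pcoa, psamples,
                                            by = "area")
    }
    out$amova_area <- amova_permutation(primary, psamples,
                                        levels = "area",
                                        n_perm = n_perm, seed = seed)
    intro <- psamples[!is.na(psamples$area) &
                        psamples$area == "introduced", , drop = FALSE]
    if (length(unique(intro$population)) >= 2) {
      sub <- marker_matrix(unclass(primary)[intro$sample_id, ,
                                            drop = FALSE])
      out$amova_population <- amova_permutation(sub, intro,
                                                levels = "population",
                                                n_perm = n_perm,
                                                seed = seed)
    }
  }
  if (!is.null(crosses) && nrow(crosses) > 0) {
    intro_pops <- unique(psamples$population[
      !is.na(psamples$area) & psamples$area == "introduced"])
    out$crossing <- infer_crossing_groups(crosses,
                                          populations = intro_pops)
    grouped <- sum(out$crossing$membership$group != "unknown")
    out$mate_availability <- if (grouped >= 2)
      mate_availability(out$crossing) else NA_real_
  }
  if (!is.null(traits)) {
    out$traits <- trait_summaries(traits, psamples)
    idx <- population_indices(primary, psamples, out)
    out$correlations <- tryCatch(
      suppressWarnings(correlation_suite(idx)),
      error = function(e) NULL)
  }
  if (!is.null(psamples$latitude) &&
      sum(!is.na(psamples$latitude)) > 2) {
    intro <- psamples[!is.na(psamples$area) &
                        psamples$area == "introduced", , drop = FALSE]
    if (length(unique(intro$population)) >= 4) {
      sub <- marker_matrix(unclass(primary)[intro$sample_id, ,
                                            drop = FALSE])
      gen <- population_distance(nei_li_dist(sub), intro)
      geo <- geo_dist_km(intro)
      common <- intersect(rownames(gen), rownames(geo))
      out$geo_genetic <- geo_genetic_correlation(
        geo[common, common], gen[common, common],
        n_perm = n_perm, seed = seed)
    }
  }
  structure(out, class = "aflp_report")
}

trait_summaries <- function(traits, samples) {
  out <- list()
  if (!is.null(traits$flowers)) {
    out$mutants <- mutant_flower_frequency(traits$flowers, samples)
    ali <- traits$flowers[, paste0("a", 1:10)]
    pol <- pollen_total(ali)
    out$pollen <- data.frame(
      population = traits$flowers$population, pollen = pol,
      ovules = traits$flowers$ovule_count,
      po_ratio = pollen_ovule_ratio(pol, traits$flowers$ovule_count),
      stringsAsFactors = FALSE)
  }
  out$seeds <- seed_summaries(traits)
  out
}

# assemble the per-population table the correlation suite consumes
population_indices <- function(marker, samples, report) {
  idx <- report$diversity_population
  names(idx)[names(idx) == "group"] <- "population"
  if (!is.null(report$clonal_stats)) {
    cs <- report$clonal_stats
    cs <- cs[cs$level == "population", c("group", "clonal_fraction")]
    idx$clonal_fraction <- cs$clonal_fraction[
      match(idx$population, cs$group)]
  }
  tr <- report$traits
  if (!is.null(tr$pollen)) {
    pm <- stats::aggregate(tr$pollen[, c("pollen", "ovules")],
                           by = list(population = tr$pollen$population),
                           FUN = mean)
    idx <- merge(idx, pm, by = "population", all.x = TRUE)
  }
  if (!is.null(tr$mutants)) {
    mm <- tr$mutants$per_population
    idx$mutant_fraction <- mm$fraction[match(idx$population,
                                             mm$population)]
  }
  idx
}

#' @export
print.aflp_report <- function(x, ...) {
  cat("dominant-marker pipeline report\n")
  if (!is.null(x$error_rate)) print(x$error_rate)
  if (!is.null(x$clones)) print(x$clones)
  if (!is.null(x$pcoa)) print(x$pcoa)
  if (!is.null(x$amova_area)) {
    cat(sprintf("AMOVA among areas: %.2f%% (phi_ST = %.3f, p = %.4f)\n",
                x$amova_area$table$pct_variance[1],
                x$amova_area$phi["phi_ST"],
                x$amova_area$p_values["phi_ST"]))
  }
  if (!is.null(x$crossing)) print(x$crossing)
  if (!is.null(x$mate_availability))
    cat(sprintf("mate availability: %.3f\n", x$mate_availability))
  if (!is.null(x$geo_genetic))
    cat(sprintf("genetic~geographic Mantel: r = %.3f, p = %.4f (%d pairs)\n",
                x$geo_genetic$r, x$geo_genetic$p_value,
                x$geo_genetic$n_pairs))
  invisible(x)
}
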