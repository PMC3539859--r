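#' Per-group fragment classes
#'
#' For each group of samples, counts fragments (loci) that are polymorphic
#' (band both present and absent among the group's scored members), fixed
#' (present in every scored member), and private (present in at least one
#' member of the group and in no scored sample outside it). The percentage
#' of polymorphic fragments is relative to the total locus count.
#'
#' @param x a [marker_matrix()].
#' @param grouping named character vector mapping sample id to group, or a
#'   [sample_frame()] plus `by` giving the grouping column.
#' @param by grouping column name when `grouping` is a sample frame
#'   (default `"population"`).
#' @return data.frame: `group`, `n_samples`, `frag_polymorphic`,
#'   `pct_polymorphic`, `frag_fixed`, `frag_private`.
#' @export
fragment_classes <- function(x, grouping, by = "population") {
  grouping <- as_grouping(grouping, rownames(x), by)
  groups <- sort(unique(grouping))
  m <- unclass(x)[names(grouping), , drop = FALSE]
  pres <- (m == 1L) & !is.na(m)
  scored <- !is.na(m)
  out <- lapply(groups, function(g) {
    inside <- grouping == g
    if (!any(inside)) stop("empty group: ", g)
    n_pres_in <- colSums(pres[inside, , drop = FALSE])
    n_scored_in <- colSums(scored[inside, , drop = FALSE])
    n_pres_out <- colSums(pres[!inside, , drop = FALSE])
    polym <- sum(n_pres_in >= 1 & n_pres_in < n_scored_in)
    fixed <- sum(n_scored_in > 0 & n_pres_in == n_scored_in)
    priv <- sum(n_pres_in >= 1 & n_pres_out == 0)
    data.frame(group = g, n_samples = sum(inside),
               frag_polymorphic = polym,
               pct_polymorphic = 100 * polym / ncol(m),
               frag_fixed = fixed, frag_private = priv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

as_grouping <- function(grouping, ids, by) {
  if (inherits(grouping, "sample_frame") ||
      (is.data.frame(grouping) && "sample_id" %in% names(grouping))) {
    if (!by %in% names(grouping)) stop("no grouping column '", by, "'")
    g <- stats::setNames(as.character(grouping[[by]]), grouping$sample_id)
    grouping <- g
  }
  grouping <- grouping[names(grouping) %in% ids]
  grouping <- grouping[!is.na(grouping)]
  if (length(grouping) == 0) stop("grouping matches no sample in the matrix")
  grouping
}

#' Classify fragments as rare or common within and between areas
#'
#' Fragment frequency is the presence fraction among the scored samples of
#' an area. A fragment is area-specific when present in only one area;
#' shared when present in both. It is rare when its frequency is below
#' `threshold` in every area where it is present.
#'
#' @param x a [marker_matrix()].
#' @param areas named character vector (sample id -> area) or
#'   [sample_frame()] with an `area` column; exactly two areas expected.
#' @param threshold rarity frequency threshold in (0, 1), default 0.15.
#' @return list with `per_fragment` (locus-level classification) and
#'   `counts` (table of specificity x rarity).
#' @export
rare_fragments <- function(x, areas, threshold = 0.15) {
  stopifnot(threshold > 0, threshold < 1)
  areas <- as_grouping(areas, rownames(x), "area")
  lv <- sort(unique(areas))
  if (length(lv) != 2) stop("exactly two areas expected; got ", length(lv))
  m <- unclass(x)[names(areas), , drop = FALSE]
  freq <- sapply(lv, function(a) {
    sub <- m[areas == a, , drop = FALSE]
    colSums(sub == 1L, na.rm = TRUE) / colSums(!is.na(sub))
  })
  present <- freq > 0
  specificity <- ifelse(present[, 1] & present[, 2], "shared",
                 ifelse(present[, 1], paste0(lv[1], "-specific"),
                 ifelse(present[, 2], paste0(lv[2], "-specific"), "absent")))
  rare <- rep(NA, ncol(m))
  for (l in seq_len(ncol(m))) {
    where <- which(present[l, ])
    if (length(where) > 0) rare[l] <- all(freq[l, where] < threshold)
  }
  per_fragment <- data.frame(locus = colnames(m),
                             freq, specificity = specificity, rare = rare,
                             stringsAsFactors = FALSE)
  names(per_fragment)[2:3] <- paste0("freq_", lv)
  counts <- table(specificity = specificity,
                  rarity = ifelse(is.na(rare), "absent",
                                  ifelse(rare, "rare", "common")))
  list(per_fragment = per_fragment, counts = counts, threshold = threshold)
}

#' Nei's gene diversity from band-phenotype frequencies
#'
#' Per locus, the unbiased two-state diversity
#' `h = (n/(n-1)) * (1 - p^2 - q^2)` with `p` the band-presence fraction
#' among the locus's `n` scored group members and `q = 1 - p`; `Hj` is the
#' mean over loci. At very small `n` the `n/(n-1)` correction can push `h`
#' above 0.5 (and to 1.0 at n = 2, p = 0.5); no cap is applied. The standard
#' deviation and variance of `Hj` come from a seeded bootstrap over loci.
#' Optionally, allele frequencies can first be back-transformed from band
#' phenotypes under a pure-recessive model (`allele_freq = "sqrt"`:
#' `q_allele = sqrt(freq(band absent))`).
#'
#' @param x a [marker_matrix()].
#' @param group character vector of sample ids forming the group
#'   (default: all rows).
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param allele_freq `"phenotype"` (default) or `"sqrt"`.
#' @return list: `hj`, `sd`, `var`, `per_locus`, `n_boot`.
#' @export
gene_diversity_hj <- function(x, group = rownames(x), n_boot = 1000,
                              seed = 1L, allele_freq = c("phenotype", "sqrt")) {
  allele_freq <- match.arg(allele_freq)
  m <- unclass(x)[group, , drop = FALSE]
  if (nrow(m) < 2) stop("gene diversity needs at least 2 samples")
  n <- colSums(!is.na(m))
  p <- colSums(m == 1L, na.rm = TRUE) / n
  if (allele_freq == "sqrt") {
    q <- sqrt(pmin(1, 1 - p))   # recessive (band-absent) allele frequency
    p <- 1 - q
  }
  h <- ifelse(n >= 2, n / (n - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
  usable <- !is.na(h)
  if (!any(usable)) stop("no locus scored in >= 2 group members")
  hj <- mean(h[usable])
  boot <- NULL
  if (n_boot > 0) {
    hs <- h[usable]
    set.seed(seed)
    boot <- replicate(n_boot, mean(hs[sample.int(length(hs),
                                                 replace = TRUE)]))
  }
  sd_out <- if (is.null(boot)) NA_real_ else stats::sd(boot)
  list(hj = hj, sd = sd_out, var = sd_out^2, per_locus = h, n_boot = n_boot)
}

#' Combined diversity table per grouping
#'
#' One row per group with fragment classes and Nei's gene diversity; the
#' usual per-population / per-area summary table of a dominant-marker study.
#'
#' @param x a [marker_matrix()].
#' @param samples a [sample_frame()].
#' @param by grouping column (default `"population"`).
#' @param n_boot,seed bootstrap control for [gene_diversity_hj()].
#' @return data.frame with fragment-class columns plus `hj`, `hj_sd`,
#'   `hj_var`.
#' @export
diversity_table <- function(x, samples, by = "population",
                            n_boot = 1000, seed = 1L) {
  fc <- fragment_classes(x, samples, by = by)
  grouping <- as_grouping(samples, rownames(x), by)
  hj <- lapply(fc$group, function(g) {
    members <- names(grouping)[grouping == g]
    if (length(members) < 2)
      return(list(hj = NA_real_, sd = NA_real_, var = NA_real_))
    gene_diversity_hj(x, members, n_boot = n_boot, seed = seed)
  })
  fc$hj <- vapply(hj, `[[`, numeric(1), "hj")
  fc$hj_sd <- vapply(hj, `[[`, numeric(1), "sd")
  fc$hj_var <- vapply(hj, `[[`, numeric(1), "var")
  fc
}
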