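#' Spearman rank correlation
#'
#' Average-rank ties; two-sided p-value from the asymptotic t
#' approximation, or from a seeded permutation of one variable.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed integer seed for the permutation.
#' @return object of class `correlation_result`: list with `r`, `p_value`,
#'   `n`, `method` (and `seed`, `n_perm` for permutation).
#' @export
spearman_cor <- function(x, y, method = c("asymptotic", "permutation"),
                         n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; Spearman correlation undefined")
  r <- stats::cor(x, y, method = "spearman")
  if (method == "asymptotic") {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    p <- ct$p.value
    out <- list(r = r, p_value = p, n = length(x), method = method)
  } else {
    set.seed(seed)
    perm <- replicate(n_perm,
                      abs(stats::cor(x, y[sample.int(length(y))],
                                     method = "spearman")))
    p <- (sum(perm >= abs(r)) + 1) / (n_perm + 1)
    out <- list(r = r, p_value = p, n = length(x), method = method,
                n_perm = n_perm, seed = seed)
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f, p = %.4g (n = %d, %s)\n",
              x$r, x$p_value, x$n, x$method))
  invisible(x)
}

#' Great-circle distances between populations (km)
#'
#' Haversine distances on decimal-degree coordinates. With
#' `planar = TRUE`, plain Euclidean distance on the coordinate columns is
#' used instead (for projected coordinates).
#'
#' @param samples a [sample_frame()] with `latitude` and `longitude` (the
#'   per-population mean of its samples is used), or a data.frame with one
#'   row per `population`.
#' @param planar use Euclidean distance on the raw coordinates.
#' @return square symmetric matrix (km) with populations as dimnames.
#' @export
geo_dist_km <- function(samples, planar = FALSE) {
  stopifnot(all(c("population", "latitude", "longitude") %in%
                  names(samples)))
  coords <- stats::aggregate(samples[, c("longitude", "latitude")],
                             by = list(population = samples$population),
                             FUN = mean, na.rm = TRUE)
  coords <- coords[!is.na(coords$longitude) & !is.na(coords$latitude), ]
  m <- as.matrix(coords[, c("longitude", "latitude")])
  if (planar) {
    d <- as.matrix(stats::dist(m))
  } else {
    d <- geosphere::distm(m, fun = geosphere::distHaversine) / 1000
  }
  dimnames(d) <- list(coords$population, coords$population)
  structure(d, metric = "geographic", class = c("band_dist", "matrix"))
}

#' Mean between-population genetic distance
#'
#' Aggregates a sample-level distance matrix (e.g. [nei_li_dist()]) to a
#' population-level one by averaging across all between-population sample
#' pairs; the diagonal is zero.
#'
#' @param d sample-level square distance matrix.
#' @param samples a [sample_frame()] covering the rows of `d`.
#' @return population-level square symmetric distance matrix.
#' @export
population_distance <- function(d, samples) {
  d <- as.matrix(d)
  pop <- samples$population[match(rownames(d), samples$sample_id)]
  if (anyNA(pop)) stop("sample(s) missing from metadata")
  pops <- sort(unique(pop))
  out <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    out[i, j] <- out[j, i] <-
      mean(d[pop == pops[i], pop == pops[j]], na.rm = TRUE)
  }
  out
}

#' Spearman correlation between genetic and geographic distances
#'
#' Correlates the unordered population-pair entries of two distance
#' matrices; because pairs sharing a population are not independent,
#' significance comes from a Mantel-style matrix permutation (rows and
#' columns permuted together), seeded.
#'
#' @param geo,gen square symmetric distance matrices over the same
#'   population set (order may differ; matched by dimnames).
#' @param n_perm number of matrix permutations (default 999).
#' @param seed integer seed.
#' @return a `correlation_result` with `n_pairs` (unordered pairs used) and
#'   the Mantel permutation p-value.
#' @export
geo_genetic_correlation <- function(geo, gen, n_perm = 999, seed = 1L) {
  geo <- as.matrix(geo); gen <- as.matrix(gen)
  if (is.null(rownames(geo)) || is.null(rownames(gen)))
    stop("distance matrices need population dimnames")
  if (!setequal(rownames(geo), rownames(gen)))
    stop("population sets differ between the two matrices")
  gen <- gen[rownames(geo), rownames(geo)]
  n <- nrow(geo)
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                      method = "spearman", permutations = n_perm)
  structure(list(r = unname(mt$statistic), p_value = mt$signif,
                 n = n, n_pairs = n * (n - 1) / 2,
                 method = "mantel_permutation",
                 n_perm = n_perm, seed = seed),
            class = "correlation_result")
}

#' The trait-diversity Spearman correlation suite
#'
#' Correlates per-population reproductive traits with per-population
#' genetic indices in one call: pollen production against polymorphic,
#' private and fixed fragment counts, gene diversity and clonal
#' percentage; mutant-flower fraction against pollen and against
#' polymorphic and private fragments; gene diversity against clonal and
#' non-clonal proportions; ovule number against mutant fraction. A
#' Holm-adjusted column is reported alongside the raw p-values. Pairs with
#' fewer than 3 shared populations or a constant variable are skipped with
#' a warning.
#'
#' @param indices data.frame keyed by `population` with (any of) columns
#'   `pollen`, `ovules`, `mutant_fraction`, `frag_polymorphic`,
#'   `frag_private`, `frag_fixed`, `hj`, `clonal_fraction`.
#' @param pairs optional two-column character matrix of variable pairs to
#'   override the default suite.
#' @return data.frame: `var_x`, `var_y`, `r`, `p_value`, `p_holm`, `n`.
#' @export
correlation_suite <- function(indices, pairs = NULL) {
  stopifnot("population" %in% names(indices))
  if ("clonal_fraction" %in% names(indices) &&
      !"nonclonal_fraction" %in% names(indices))
    indices$nonclonal_fraction <- 1 - indices$clonal_fraction
  if (is.null(pairs)) {
    pairs <- rbind(
      c("pollen", "frag_polymorphic"),
      c("pollen", "hj"),
      c("pollen", "frag_private"),
      c("pollen", "frag_fixed"),
      c("pollen", "clonal_fraction"),
      c("mutant_fraction", "pollen"),
      c("mutant_fraction", "frag_polymorphic"),
      c("mutant_fraction", "frag_private"),
      c("hj", "clonal_fraction"),
      c("hj", "nonclonal_fraction"),
      c("ovules", "mutant_fraction"))
  }
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    vx <- pairs[k, 1]; vy <- pairs[k, 2]
    if (!vx %in% names(indices) || !vy %in% names(indices)) next
    x <- indices[[vx]]; y <- indices[[vy]]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0 ||
        stats::sd(y[keep]) == 0) {
      warning("pair ", vx, " ~ ", vy,
              " skipped (too few populations or constant variable)")
      next
    }
    sc <- spearman_cor(x[keep], y[keep])
    rows[[length(rows) + 1]] <-
      data.frame(var_x = vx, var_y = vy, r = sc$r, p_value = sc$p_value,
                 n = sc$n, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(var_x = character(), var_y = character(),
                      r = numeric(), p_value = numeric(),
                      p_holm = numeric(), n = integer()))
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out[, c("var_x", "var_y", "r", "p_value", "p_holm", "n")]
}
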