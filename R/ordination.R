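#' Nei & Li (Dice) distances between band phenotypes
#'
#' For each pair of samples, over jointly scored loci:
#' `S = 2*n11 / (2*n11 + n10 + n01)` (n11 shared bands, n10/n01 bands unique
#' to either sample) and `d = 1 - S`. Pairs with no bands on either side
#' (`n11 + n10 + n01 = 0`) get a missing distance with a warning.
#'
#' @param x a [marker_matrix()].
#' @return square symmetric matrix of class `band_dist` with attribute
#'   `metric = "nei_li"`.
#' @export
nei_li_dist <- function(x) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  m <- unclass(x)
  P <- (m == 1L) & !is.na(m); storage.mode(P) <- "double"
  A <- (m == 0L) & !is.na(m); storage.mode(A) <- "double"
  n11 <- P %*% t(P)
  n10 <- P %*% t(A)          # band in row sample only
  denom <- 2 * n11 + n10 + t(n10)
  d <- 1 - ifelse(denom > 0, 2 * n11 / denom, NA_real_)
  if (any(denom == 0 & upper.tri(denom)))
    warning("sample pair(s) share no scored bands; Nei-Li distance missing")
  diag(d) <- 0
  structure(d, metric = "nei_li", class = c("band_dist", "matrix"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a distance matrix into orthogonal axes by double-centering
#' `-d^2/2` and eigendecomposition; coordinates are eigenvectors scaled by
#' the square root of their (positive) eigenvalues. Percent variance per
#' axis is taken over the positive eigenvalues; negative eigenvalues are
#' counted and reported, and no correction is applied unless requested.
#'
#' @param d square symmetric distance matrix (e.g. [nei_li_dist()]) or
#'   `dist` object, without missing cells.
#' @param correction `"none"` (default) or `"cailliez"` (additive constant
#'   making the configuration Euclidean).
#' @return object of class `band_pcoa`: list with `coordinates`
#'   (samples x axes, columns `Axis1..`), `eigenvalues` (all, decreasing),
#'   `pct_variance` (per positive axis, sums to 100), `n_negative`.
#' @export
band_pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (anyNA(d))
    stop("distance matrix has missing cells; impute or subset samples first")
  n <- nrow(d)
  dd <- stats::as.dist(d)
  if (correction == "cailliez") dd <- add_cailliez(dd)
  res <- suppressWarnings(stats::cmdscale(dd, k = n - 1, eig = TRUE))
  eig <- res$eig
  pos <- eig > max(eig) * 1e-9
  coords <- res$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 pct_variance = 100 * eig[pos] / sum(eig[pos]),
                 n_negative = sum(eig < -max(eig) * 1e-9)),
            class = "band_pcoa")
}

# Cailliez additive constant: smallest c with d + c Euclidean.
add_cailliez <- function(dd) {
  d <- as.matrix(dd)
  n <- nrow(d)
  J <- diag(n) - 1 / n
  D1 <- -0.5 * J %*% (d^2) %*% J
  D2 <- -0.5 * J %*% d %*% J
  B <- rbind(cbind(matrix(0, n, n), 2 * D1),
             cbind(-diag(n), -4 * D2))
  cstar <- max(Re(eigen(B, only.values = TRUE)$values))
  out <- d + cstar
  diag(out) <- 0
  stats::as.dist(out)
}

#' @export
print.band_pcoa <- function(x, ...) {
  k <- min(3, length(x$pct_variance))
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_negative))
  cat(sprintf("  first %d axes: %s%% of variance (total %.2f%%)\n", k,
              paste(sprintf("%.2f", x$pct_variance[1:k]), collapse = ", "),
              sum(x$pct_variance[1:k])))
  invisible(x)
}

#' Rank tests of group separation on ordination axes
#'
#' Per axis: Mann-Whitney U (two groups; average-rank ties, normal
#' approximation without continuity correction) or Kruskal-Wallis H (more
#' than two groups), with two-sided p-values.
#'
#' @param pcoa a [band_pcoa()] result (or a coordinate matrix).
#' @param grouping named character vector (sample -> group) or
#'   [sample_frame()] with `by`.
#' @param axes integer vector of axes to test (default `1:3`, truncated to
#'   what exists).
#' @param by grouping column when `grouping` is a sample frame.
#' @return data.frame: `axis`, `test`, `statistic`, `p_value`, group sizes.
#' @export
axis_group_test <- function(pcoa, grouping, axes = 1:3, by = "population") {
  coords <- if (inherits(pcoa, "band_pcoa")) pcoa$coordinates else as.matrix(pcoa)
  grouping <- as_grouping(grouping, rownames(coords), by)
  coords <- coords[names(grouping), , drop = FALSE]
  groups <- sort(unique(grouping))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(grouping) == 0)) stop("empty group")
  axes <- axes[axes <= ncol(coords)]
  out <- lapply(axes, function(ax) {
    v <- coords[, ax]
    if (length(groups) == 2) {
      w <- stats::wilcox.test(v[grouping == groups[1]],
                              v[grouping == groups[2]],
                              exact = FALSE, correct = FALSE)
      data.frame(axis = ax, test = "mann_whitney_u",
                 statistic = unname(w$statistic), p_value = w$p.value,
                 n1 = sum(grouping == groups[1]),
                 n2 = sum(grouping == groups[2]), stringsAsFactors = FALSE)
    } else {
      k <- stats::kruskal.test(v, factor(grouping))
      data.frame(axis = ax, test = "kruskal_wallis_h",
                 statistic = unname(k$statistic), p_value = k$p.value,
                 n1 = length(v), n2 = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
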