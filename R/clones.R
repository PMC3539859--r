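#' Replicate-based genotyping error rate
#'
#' The error rate of a dominant-marker run is estimated from replicate pairs
#' (independent re-extractions/re-scorings of the same individual) as the
#' number of genotype mismatches divided by (number of replicate pairs x
#' number of loci). Mismatches are counted only at loci scored in both
#' members of a pair, but the denominator is always the full locus count, so
#' missing cells can only lower the estimate.
#'
#' @param n_mismatches total mismatching loci over all replicate pairs.
#' @param n_pairs number of replicate pairs.
#' @param n_loci total number of loci.
#' @return object of class `error_rate` with fields `n_mismatches`,
#'   `n_pairs`, `n_loci`, `rate`.
#' @examples
#' error_rate(123, 9, 294)  # rate 0.0465
#' @export
error_rate <- function(n_mismatches, n_pairs, n_loci) {
  stopifnot(n_mismatches >= 0, n_pairs >= 1, n_loci >= 1)
  rate <- n_mismatches / (n_pairs * n_loci)
  if (rate > 1) stop("error rate above 1: more mismatches than pair-loci")
  structure(list(n_mismatches = n_mismatches, n_pairs = n_pairs,
                 n_loci = n_loci, rate = rate),
            class = "error_rate")
}

#' @export
print.error_rate <- function(x, ...) {
  cat(sprintf("replicate error rate: %d mismatches / (%d pairs x %d loci) = %.4f (%.2f%%)\n",
              x$n_mismatches, x$n_pairs, x$n_loci, x$rate, 100 * x$rate))
  invisible(x)
}

#' Estimate the error rate from replicate pairs in a marker matrix
#'
#' @param x a [marker_matrix()].
#' @param pairs two-column data.frame/matrix of sample ids (`sample`,
#'   `replicate`), or a [sample_frame()] with a `replicate_of` column from
#'   which the pairs are taken.
#' @return an [error_rate()] object.
#' @export
replicate_error_rate <- function(x, pairs) {
  if (inherits(pairs, "sample_frame") ||
      (is.data.frame(pairs) && "replicate_of" %in% names(pairs))) {
    keep <- !is.na(pairs$replicate_of)
    pairs <- data.frame(sample = pairs$replicate_of[keep],
                        replicate = pairs$sample_id[keep],
                        stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stop("no replicate pairs supplied")
  ids <- rownames(x)
  for (col in 1:2) {
    missing_ids <- setdiff(pairs[[col]], ids)
    if (length(missing_ids) > 0)
      stop("replicate pair member(s) not in matrix: ",
           paste(missing_ids, collapse = ", "))
  }
  mism <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- unclass(x)[pairs[[1]][k], ]
    b <- unclass(x)[pairs[[2]][k], ]
    mism <- mism + sum(a != b, na.rm = TRUE)
  }
  error_rate(mism, nrow(pairs), ncol(x))
}

#' Pairwise mismatch fractions between samples
#'
#' For every pair of samples: the fraction of mismatching loci among loci
#' scored in both (pairwise deletion). Pairs with no jointly scored locus
#' get a missing distance and a warning.
#'
#' @param x a [marker_matrix()].
#' @return object of class `mismatch_matrix`: list with `d` (square,
#'   symmetric, zero diagonal) and `n_scored` (jointly scored loci per pair).
#' @export
pairwise_mismatch <- function(x) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  m <- unclass(x)
  P <- (m == 1L) & !is.na(m); storage.mode(P) <- "double"
  A <- (m == 0L) & !is.na(m); storage.mode(A) <- "double"
  S <- !is.na(m); storage.mode(S) <- "double"
  n_scored <- S %*% t(S)
  diffs <- P %*% t(A) + A %*% t(P)
  d <- diffs / n_scored
  if (any(n_scored == 0 & upper.tri(n_scored)))
    warning("sample pair(s) with no jointly scored loci; distance set missing")
  d[n_scored == 0] <- NA_real_
  diag(d) <- 0
  structure(list(d = d, n_scored = n_scored), class = "mismatch_matrix")
}

#' Partition samples into clonal lineages by the error-rate threshold
#'
#' Two samples are linked when their pairwise mismatch fraction is strictly
#' below the genotyping error rate; clonal lineages are the connected
#' components (single-linkage closure) of that graph. Triples where two
#' links hold but the closing pair does not are non-transitive: they are
#' flagged in the output rather than broken.
#'
#' @param d a [pairwise_mismatch()] result.
#' @param threshold an [error_rate()] object or a plain fraction.
#' @return object of class `clone_partition`: list with `assignments`
#'   (data.frame `sample_id`, `lineage`), `threshold`, `sizes` (per-lineage
#'   member counts), `triples` (flagged non-transitive triples).
#'   Lineages are labelled `c1`, `c2`, ... by decreasing size; singletons
#'   get their own lineage id.
#' @export
call_clones <- function(d, threshold) {
  if (inherits(threshold, "error_rate")) threshold <- threshold$rate
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  dm <- d$d
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dm)))
  adj <- !is.na(dm) & dm < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel by decreasing size, ties by first sample index
  sizes <- table(comp)
  first_idx <- tapply(seq_along(comp), comp, min)
  ord <- order(-as.integer(sizes), first_idx)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  lineage <- paste0("c", relabel[comp])
  assignments <- data.frame(sample_id = ids, lineage = lineage,
                            stringsAsFactors = FALSE)
  triples <- flag_nontransitive(adj, dm, ids)
  sizes_out <- sort(table(lineage), decreasing = TRUE)
  structure(list(assignments = assignments,
                 threshold = threshold,
                 sizes = sizes_out,
                 triples = triples),
            class = "clone_partition")
}

# triples (a,b,c) with edges a-b and b-c but no edge a-c; a-c pairs with a
# missing distance are excluded from flagging (and from clone calling).
flag_nontransitive <- function(adj, dm, ids) {
  common <- (adj %*% adj) > 0
  cand <- which(common & !adj & upper.tri(adj) & !is.na(dm), arr.ind = TRUE)
  out <- data.frame(a = character(), via = character(), c = character(),
                    d_ac = numeric(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    via <- which(adj[i, ] & adj[j, ])
    out <- rbind(out, data.frame(
      a = ids[i], via = paste(ids[via], collapse = ";"), c = ids[j],
      d_ac = dm[i, j], stringsAsFactors = FALSE))
  }
  out
}

#' Build a clone partition from an explicit assignment table
#'
#' @param assignments data.frame with `sample_id` and `lineage` columns.
#' @param threshold the mismatch threshold that produced it (may be `NA`).
#' @return a `clone_partition`.
#' @export
clone_partition <- function(assignments, threshold = NA_real_) {
  stopifnot(all(c("sample_id", "lineage") %in% names(assignments)))
  if (anyDuplicated(assignments$sample_id))
    stop("duplicate sample_id in assignments")
  structure(list(assignments = assignments, threshold = threshold,
                 sizes = sort(table(assignments$lineage), decreasing = TRUE),
                 triples = NULL),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  multi <- sum(x$sizes[x$sizes >= 2])
  cat(sprintf("clone partition: %d samples, %d lineages (%d multi-member holding %d samples), threshold %.4f\n",
              nrow(x$assignments), length(x$sizes), sum(x$sizes >= 2), multi,
              x$threshold))
  if (!is.null(x$triples) && nrow(x$triples) > 0)
    cat(sprintf("  %d non-transitive triple(s) flagged\n", nrow(x$triples)))
  invisible(x)
}

#' Per-group clonality summary
#'
#' A sample counts as clonal when it belongs to a lineage with two or more
#' members anywhere in the data set (so a lineage spanning populations is
#' counted once globally, but its members count in each population's clonal
#' tally). The clonal fraction of a group is clonal members / samples.
#'
#' @param partition a [call_clones()] / [clone_partition()] result.
#' @param samples a [sample_frame()] covering every partitioned sample.
#' @return data.frame with one row per population, per area (when an `area`
#'   column exists) and a final `all` row; columns `level`, `group`,
#'   `n_samples`, `n_clonal`, `n_lineages`, `clonal_fraction`.
#' @export
clonal_stats <- function(partition, samples) {
  asg <- partition$assignments
  idx <- match(asg$sample_id, samples$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from sample frame: ",
         paste(asg$sample_id[is.na(idx)], collapse = ", "))
  global_sizes <- table(asg$lineage)
  multi <- names(global_sizes)[global_sizes >= 2]
  is_clonal <- asg$lineage %in% multi
  grp_summary <- function(which_rows, level, label) {
    sub <- asg[which_rows, , drop = FALSE]
    data.frame(level = level, group = label,
               n_samples = nrow(sub),
               n_clonal = sum(is_clonal[which_rows]),
               n_lineages = length(unique(sub$lineage)),
               clonal_fraction = if (nrow(sub) > 0)
                 sum(is_clonal[which_rows]) / nrow(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }
  pop <- samples$population[idx]
  out <- do.call(rbind, lapply(sort(unique(pop)), function(p)
    grp_summary(which(pop == p), "population", p)))
  if (!is.null(samples$area)) {
    area <- samples$area[idx]
    out <- rbind(out, do.call(rbind, lapply(
      sort(unique(area[!is.na(area)])), function(a)
        grp_summary(which(!is.na(area) & area == a), "area", a))))
  }
  out <- rbind(out, grp_summary(seq_len(nrow(asg)), "all", "all"))
  rownames(out) <- NULL
  out
}
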