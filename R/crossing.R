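#' Classify crossing outcomes per unordered population pair
#'
#' Records for both directions of a pair are pooled. A pair is
#' `compatible` when the pooled seed total is positive, `incompatible`
#' when it was tested (at least `min_flowers` flowers) yet set no seed, and
#' `untested` otherwise. Capsules without seeds do not confer
#' compatibility. Intra-population records classify the population against
#' itself. With `pool_directions = FALSE`, each direction is classified
#' separately as well.
#'
#' @param crosses a [cross_table()].
#' @param min_flowers minimum pooled flower count before a seedless pair is
#'   declared incompatible (default 1).
#' @param pool_directions pool reciprocal directions (default `TRUE`).
#' @return data.frame: `pop_a`, `pop_b` (sorted within pair), `n_flowers`,
#'   `n_capsules`, `n_seeds`, `outcome`; with `pool_directions = FALSE` an
#'   extra `direction` column keeps each direction's record.
#' @export
classify_crosses <- function(crosses, min_flowers = 1,
                             pool_directions = TRUE) {
  stopifnot(inherits(crosses, "cross_table") || is.data.frame(crosses))
  if (nrow(crosses) == 0)
    return(data.frame(pop_a = character(), pop_b = character(),
                      n_flowers = integer(), n_capsules = integer(),
                      n_seeds = integer(), outcome = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(crosses$mother_population, crosses$father_population)
  b <- pmax(crosses$mother_population, crosses$father_population)
  key <- if (pool_directions) paste(a, b, sep = "\r") else
    paste(crosses$mother_population, crosses$father_population, sep = "\r")
  agg <- function(v) tapply(v, key, sum)
  fl <- agg(crosses$n_flowers); cp <- agg(crosses$n_capsules)
  sd_ <- agg(crosses$n_seeds)
  keys <- names(fl)
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  outcome <- ifelse(sd_ > 0, "compatible",
                    ifelse(fl >= min_flowers, "incompatible", "untested"))
  out <- data.frame(pop_a = pmin(ab[, 1], ab[, 2]),
                    pop_b = pmax(ab[, 1], ab[, 2]),
                    n_flowers = as.integer(fl),
                    n_capsules = as.integer(cp),
                    n_seeds = as.integer(sd_),
                    outcome = unname(outcome),
                    stringsAsFactors = FALSE)
  if (!pool_directions)
    out$direction <- paste(ab[, 1], ab[, 2], sep = " x ")
  rownames(out) <- NULL
  out
}

#' Infer crossing groups (shared S-allele classes) from crossing outcomes
#'
#' A crossing group is a set of populations that never set seed when
#' crossed with each other: the connected components of the incompatibility
#' graph (edges = incompatible pairs). Compatible pairs falling inside one
#' component contradict the partition and are listed as conflicts.
#' Populations with no tested crossings (e.g. plants that never flowered)
#' are `"unknown"` and never forced into a group. Intra-population
#' incompatible crossings mark the population as self-confirmed.
#'
#' @param crosses a [cross_table()].
#' @param populations optional character vector of all candidate
#'   populations; those without records become `"unknown"`.
#' @param min_flowers passed to [classify_crosses()].
#' @return object of class `crossing_groups`: list with `membership`
#'   (data.frame `population`, `group`; `"unknown"` where ungrouped),
#'   `sizes` (per-group member counts, decreasing), `conflicts`
#'   (compatible within-group pairs), `self_incompatible` (populations with
#'   seedless intra-population crossings), `outcomes` (the classified pair
#'   table).
#' @export
infer_crossing_groups <- function(crosses, populations = NULL,
                                  min_flowers = 1) {
  oc <- classify_crosses(crosses, min_flowers = min_flowers)
  inter <- oc[oc$pop_a != oc$pop_b, , drop = FALSE]
  intra <- oc[oc$pop_a == oc$pop_b, , drop = FALSE]
  tested <- unique(c(inter$pop_a[inter$outcome != "untested"],
                     inter$pop_b[inter$outcome != "untested"],
                     intra$pop_a[intra$outcome != "untested"]))
  all_pops <- sort(unique(c(populations, oc$pop_a, oc$pop_b)))
  inc <- inter[inter$outcome == "incompatible", , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(tested), name = sort(tested))
  if (nrow(inc) > 0)
    g <- igraph::add_edges(g, rbind(match(inc$pop_a, sort(tested)),
                                    match(inc$pop_b, sort(tested))))
  comp <- if (length(tested) > 0) igraph::components(g)$membership else
    integer(0)
  # label groups by decreasing size, ties by first population name
  membership <- rep("unknown", length(all_pops))
  names(membership) <- all_pops
  if (length(comp) > 0) {
    sizes <- table(comp)
    first_pop <- tapply(names(comp), comp, min)
    ord <- order(-as.integer(sizes), first_pop)
    relabel <- integer(length(sizes))
    relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
    membership[names(comp)] <- paste0("g", relabel[comp])
  }
  grp_of <- membership
  conflicts <- inter[inter$outcome == "compatible" &
                       grp_of[inter$pop_a] != "unknown" &
                       grp_of[inter$pop_a] == grp_of[inter$pop_b], ,
                     drop = FALSE]
  sizes_out <- sort(table(membership[membership != "unknown"]),
                    decreasing = TRUE)
  structure(list(
    membership = data.frame(population = all_pops,
                            group = unname(membership),
                            stringsAsFactors = FALSE),
    sizes = sizes_out,
    conflicts = conflicts,
    self_incompatible = intra$pop_a[intra$outcome == "incompatible"],
    outcomes = oc),
    class = "crossing_groups")
}

#' @export
print.crossing_groups <- function(x, ...) {
  n_unknown <- sum(x$membership$group == "unknown")
  cat(sprintf("crossing groups: %d populations in %d groups (sizes %s); %d unknown\n",
              sum(x$membership$group != "unknown"), length(x$sizes),
              paste(as.integer(x$sizes), collapse = "/"), n_unknown))
  if (nrow(x$conflicts) > 0)
    cat(sprintf("  %d conflicting compatible within-group pair(s)\n",
                nrow(x$conflicts)))
  invisible(x)
}

#' Mate availability among grouped populations
#'
#' The fraction of unordered pairs of grouped populations whose members lie
#' in different crossing groups (and are therefore cross-compatible under
#' the shared-S-allele rule). Ungrouped (`"unknown"`) populations are
#' excluded.
#'
#' @param partition a [infer_crossing_groups()] result.
#' @return fraction in \[0, 1\].
#' @export
mate_availability <- function(partition) {
  grp <- partition$membership$group
  grp <- grp[grp != "unknown"]
  n <- length(grp)
  if (n < 2) stop("need >= 2 grouped populations")
  total <- n * (n - 1) / 2
  within <- sum(table(grp) * (table(grp) - 1) / 2)
  (total - within) / total
}
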