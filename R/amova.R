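#' Hierarchical analysis of molecular variance (AMOVA) on band data
#'
#' Partitions the molecular variance of a binary marker matrix among one or
#' two hierarchy levels. Pairwise squared distances are mismatch counts
#' (squared Euclidean on 0/1 band vectors, over jointly scored loci);
#' optionally squared Nei & Li distances. Sums of squares follow the
#' standard distance-based decomposition (total SS = sum of squared
#' distances / N; within-group SS summed per group), variance components
#' come from the expected mean squares with unequal group sizes, and
#' phi-statistics are ratios of variance components. Negative components
#' are reported as estimated; for the percent-of-variance display they are
#' truncated at zero unless `truncate_negative = FALSE`.
#'
#' @param x a [marker_matrix()], or a precomputed square matrix of squared
#'   distances.
#' @param samples a [sample_frame()] (or named vector for one level).
#' @param levels character vector of one or two grouping column names,
#'   outermost first (e.g. `c("area")` or `c("area", "population")`).
#' @param distance `"mismatch"` (default) or `"nei_li"` (squared).
#' @param truncate_negative truncate negative components at 0 for the
#'   percent display (default `TRUE`).
#' @return object of class `amova`: list with `table` (source, df, SS, MS,
#'   variance component sigma2, percent), `phi` (named vector: `phi_ST`,
#'   plus `phi_CT`, `phi_SC` for two levels), `n`, `levels`.
#' @export
amova <- function(x, samples, levels = "population",
                  distance = c("mismatch", "nei_li"),
                  truncate_negative = TRUE) {
  distance <- match.arg(distance)
  d2 <- amova_d2(x, distance)
  grp <- amova_grouping(samples, rownames(d2), levels)
  res <- amova_fit(d2, grp, truncate_negative)
  res$levels <- levels
  res
}

amova_d2 <- function(x, distance) {
  if (inherits(x, "marker_matrix")) {
    m <- unclass(x)
    P <- (m == 1L) & !is.na(m); storage.mode(P) <- "double"
    A <- (m == 0L) & !is.na(m); storage.mode(A) <- "double"
    if (distance == "mismatch") {
      d2 <- P %*% t(A) + A %*% t(P)   # mismatch count = squared Euclidean
    } else {
      d2 <- unclass(nei_li_dist(x))^2
    }
    diag(d2) <- 0
    d2
  } else {
    as.matrix(x)
  }
}

amova_grouping <- function(samples, ids, levels) {
  if (!is.data.frame(samples)) {
    stopifnot(length(levels) == 1)
    return(data.frame(g1 = as.character(samples[ids]),
                      row.names = ids, stringsAsFactors = FALSE))
  }
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from metadata: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  out <- data.frame(row.names = ids, stringsAsFactors = FALSE)
  for (k in seq_along(levels)) {
    if (!levels[k] %in% names(samples))
      stop("no metadata column '", levels[k], "'")
    out[[paste0("g", k)]] <- as.character(samples[[levels[k]]][idx])
  }
  out
}

# sum of squared distances within each index set, divided by set size
ssd <- function(d2, sets) {
  sum(vapply(sets, function(ix)
    sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix), numeric(1)))
}

amova_fit <- function(d2, grp, truncate_negative = TRUE) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  if (ncol(grp) == 1) {
    g <- grp$g1
    groups <- unique(g)
    if (length(groups) < 2) stop("need >= 2 groups at the tested level")
    sets <- split(seq_len(N), g)
    ng <- lengths(sets)
    ss_wg <- ssd(d2, sets)
    ss_ag <- ss_total - ss_wg
    df_ag <- length(groups) - 1
    df_wg <- N - length(groups)
    ms_ag <- ss_ag / df_ag
    ms_wg <- ss_wg / df_wg
    n0 <- (N - sum(ng^2) / N) / df_ag
    sig_w <- ms_wg
    sig_a <- (ms_ag - ms_wg) / n0
    comps <- c(among = sig_a, within = sig_w)
    tab <- data.frame(
      source = c("among_groups", "within_groups", "total"),
      df = c(df_ag, df_wg, N - 1),
      SS = c(ss_ag, ss_wg, ss_total),
      MS = c(ms_ag, ms_wg, NA),
      sigma2 = c(sig_a, sig_w, sig_a + sig_w),
      stringsAsFactors = FALSE)
    phi <- c(phi_ST = phi_ratio(sig_a, sig_a + sig_w))
  } else {
    g1 <- grp$g1; g2p <- paste(grp$g1, grp$g2, sep = "\r")
    groups <- unique(g1); pops <- unique(g2p)
    if (length(groups) < 2) stop("need >= 2 groups at the top level")
    sets_g <- split(seq_len(N), g1)
    sets_p <- split(seq_len(N), g2p)
    G <- length(sets_g); P <- length(sets_p)
    ss_wp <- ssd(d2, sets_p)
    ss_wg <- ssd(d2, sets_g)
    ss_ap <- ss_wg - ss_wp
    ss_ag <- ss_total - ss_wg
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    ms_ag <- ss_ag / df_ag; ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp
    np <- lengths(sets_p)
    ngrp <- lengths(sets_g)
    pop_group <- vapply(sets_p, function(ix) g1[ix[1]], character(1))
    sum_np2_by_g <- tapply(np^2, pop_group, sum)
    Ng <- tapply(np, pop_group, sum)
    n1 <- (N - sum(sum_np2_by_g / Ng)) / df_ap
    n2 <- (sum(sum_np2_by_g / Ng) - sum(np^2) / N) / df_ag
    n3 <- (N - sum(ngrp^2) / N) / df_ag
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    tab <- data.frame(
      source = c("among_groups", "among_pops_within_groups",
                 "within_pops", "total"),
      df = c(df_ag, df_ap, df_wp, N - 1),
      SS = c(ss_ag, ss_ap, ss_wp, ss_total),
      MS = c(ms_ag, ms_ap, ms_wp, NA),
      sigma2 = c(sig_a, sig_b, sig_c, tot),
      stringsAsFactors = FALSE)
    phi <- c(phi_ST = phi_ratio(sig_a + sig_b, tot),
             phi_CT = phi_ratio(sig_a, tot),
             phi_SC = phi_ratio(sig_b, sig_b + sig_c))
  }
  k <- nrow(tab) - 1
  comp <- tab$sigma2[seq_len(k)]
  disp <- if (truncate_negative) pmax(comp, 0) else comp
  pct <- if (sum(disp) > 0) 100 * disp / sum(disp) else rep(NaN, k)
  if (all(is.nan(pct))) warning("zero total variance; phi undefined")
  tab$pct_variance <- c(pct, if (all(is.nan(pct))) NaN else 100)
  structure(list(table = tab, phi = phi, n = N), class = "amova")
}

phi_ratio <- function(num, den) {
  if (is.na(den) || den == 0) return(NaN)
  num / den
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA (%d samples, levels: %s)\n", x$n,
              paste(x$levels, collapse = " / ")))
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$MS <- round(tab$MS, 3)
  tab$sigma2 <- round(tab$sigma2, 4)
  tab$pct_variance <- round(tab$pct_variance, 2)
  print(tab, row.names = FALSE)
  cat("phi: ", paste(sprintf("%s = %.3f", names(x$phi), x$phi),
                     collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("permutation p: ",
        paste(sprintf("%s = %.4f", names(x$p_values), x$p_values),
              collapse = ", "),
        sprintf(" (%d permutations)\n", x$n_permutations))
  invisible(x)
}

#' Permutation test for AMOVA phi-statistics
#'
#' Sample labels are permuted among groups at the tested level and phi
#' recomputed; `p = (# permuted phi >= observed + 1) / (n_perm + 1)`.
#' For a two-level design, `phi_ST` permutes samples across everything,
#' `phi_CT` permutes whole populations among groups, and `phi_SC` permutes
#' samples among populations within their group.
#'
#' @inheritParams amova
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return the [amova()] object with `p_values` and `n_permutations` added.
#' @export
amova_permutation <- function(x, samples, levels = "population",
                              n_perm = 999, seed = 1L,
                              distance = c("mismatch", "nei_li")) {
  stopifnot(n_perm >= 99)
  distance <- match.arg(distance)
  d2 <- amova_d2(x, distance)
  grp <- amova_grouping(samples, rownames(d2), levels)
  obs <- amova_fit(d2, grp)
  set.seed(seed)
  N <- nrow(d2)
  if (ncol(grp) == 1) {
    stat <- replicate(n_perm, {
      gp <- grp; gp$g1 <- gp$g1[sample.int(N)]
      suppressWarnings(amova_fit(d2, gp)$phi[["phi_ST"]])
    })
    p <- c(phi_ST = perm_p(stat, obs$phi[["phi_ST"]]))
  } else {
    st <- replicate(n_perm, {
      ix <- sample.int(N)
      gp <- data.frame(g1 = grp$g1[ix], g2 = grp$g2[ix],
                       stringsAsFactors = FALSE)
      suppressWarnings(amova_fit(d2, gp)$phi[["phi_ST"]])
    })
    pops <- unique(grp$g2)
    pop_of <- match(grp$g2, pops)
    group_of_pop <- grp$g1[match(pops, grp$g2)]
    ct <- replicate(n_perm, {
      gp <- grp
      gp$g1 <- group_of_pop[sample.int(length(pops))][pop_of]
      suppressWarnings(amova_fit(d2, gp)$phi[["phi_CT"]])
    })
    sc <- replicate(n_perm, {
      gp <- grp
      for (g in unique(grp$g1)) {
        ix <- which(grp$g1 == g)
        gp$g2[ix] <- grp$g2[ix][sample.int(length(ix))]
      }
      suppressWarnings(amova_fit(d2, gp)$phi[["phi_SC"]])
    })
    p <- c(phi_ST = perm_p(st, obs$phi[["phi_ST"]]),
           phi_CT = perm_p(ct, obs$phi[["phi_CT"]]),
           phi_SC = perm_p(sc, obs$phi[["phi_SC"]]))
  }
  obs$p_values <- p
  obs$n_permutations <- n_perm
  obs$seed <- seed
  obs$levels <- levels
  obs
}

perm_p <- function(stat, observed) {
  if (is.nan(observed)) return(NA_real_)
  stat <- stat[!is.nan(stat)]
  (sum(stat >= observed) + 1) / (length(stat) + 1)
}
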