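# Brute-force oracles and small fixture builders, independent of the
# package's vectorised implementations.

random_marker <- function(n, L, p_missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n * L, 1, 0.5), n, L)
  if (p_missing > 0) {
    m[runif(n * L) < p_missing] <- NA
    # keep every row scored somewhere
    for (i in seq_len(n)) if (all(is.na(m[i, ]))) m[i, 1] <- 1L
  }
  marker_matrix(m, paste0("s", seq_len(n)), paste0("L", seq_len(L)))
}

# double-loop pairwise mismatch fraction over jointly scored loci
brute_mismatch <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:n) for (j in 1:n) {
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    d[i, j] <- if (sum(both) == 0 && i != j) NA_real_ else
      if (i == j) 0 else sum(m[i, both] != m[j, both]) / sum(both)
  }
  d
}

# band tallies -> Dice distance
brute_nei_li <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    n11 <- sum(m[i, both] == 1 & m[j, both] == 1)
    n10 <- sum(m[i, both] == 1 & m[j, both] == 0)
    n01 <- sum(m[i, both] == 0 & m[j, both] == 1)
    d[i, j] <- if (2 * n11 + n10 + n01 == 0) NA_real_ else
      1 - 2 * n11 / (2 * n11 + n10 + n01)
  }
  d
}

# explicit pairwise-distance-sum AMOVA sums of squares (one level)
brute_amova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    s <- 0
    if (length(ix) > 1)
      for (a in 1:(length(ix) - 1)) for (b in (a + 1):length(ix))
        s <- s + d2[ix[a], ix[b]]
    ss_within <- ss_within + s / length(ix)
  }
  c(among = ss_total - ss_within, within = ss_within, total = ss_total)
}

# Mann-Whitney U by exhaustive pair counting (x wins + half ties)
brute_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Spearman r from average ranks, direct formula
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# crossing records reproducing the inferred structure of the motivating
# study: 13 mutually incompatible populations, one trio, three singleton
# groups attached by compatible crosses, one population never flowering.
figure2_crosses <- function() {
  green <- c("Kt", "Bz", "Re", "Hw", "Bl", "U", "Wi", "Il", "Gue", "Bg",
             "Zi", "We", "A")
  blue <- c("Tp", "Tb", "Pl")
  rec <- list()
  add <- function(a, b, fl, cp, sd_) rec[[length(rec) + 1]] <<- data.frame(
    mother_population = a, father_population = b, n_flowers = fl,
    n_capsules = cp, n_seeds = sd_, stringsAsFactors = FALSE)
  prs <- combn(green, 2)
  for (k in seq_len(ncol(prs))) add(prs[1, k], prs[2, k], 4, 1, 0)
  prs <- combn(blue, 2)
  for (k in seq_len(ncol(prs))) add(prs[1, k], prs[2, k], 4, 0, 0)
  # singleton groups tested compatibly against members of other groups
  add("Tl", "Kt", 5, 3, 9); add("Tl", "Tb", 3, 2, 6)
  add("Mue", "Bl", 4, 2, 7); add("Mue", "Mt", 4, 3, 8)
  add("Mt", "Zi", 5, 2, 5)
  # compatible between the two multi-population groups
  add("Tp", "Kt", 5, 4, 11)
  # intra-population seedless crossing
  add("Pl", "Pl", 41, 0, 0)
  cross_table(do.call(rbind, rec))
}

all_introduced_pops <- function() {
  c("Tp", "Tb", "Tl", "Kt", "Pl", "Bz", "Re", "Hw", "Mue", "Mt", "Bl",
    "U", "Wi", "Il", "Gue", "Bg", "Zi", "Gss", "We", "A")
}
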