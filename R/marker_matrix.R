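#' Construct a binary marker (band presence/absence) matrix
#'
#' The central container of the package: a samples x loci matrix of dominant
#' marker scores, `1` = band present, `0` = band absent, `NA` = not scored.
#' All genetic statistics in the package operate on this object; missing
#' cells are excluded pairwise from every statistic.
#'
#' @param band numeric/integer matrix with entries in \{0, 1, NA\}.
#' @param sample_ids optional character vector of unique row labels
#'   (defaults to `rownames(band)`).
#' @param locus_ids optional character vector of unique column labels
#'   (defaults to `colnames(band)`, or `L1..Lk`).
#' @return An object of class `marker_matrix`: an integer matrix with
#'   dimnames set and invariants checked.
#' @examples
#' mm <- marker_matrix(rbind(s1 = c(1, 0, 1), s2 = c(0, 0, 1)))
#' dim(mm)
#' @export
marker_matrix <- function(band, sample_ids = NULL, locus_ids = NULL) {
  band <- as.matrix(band)
  if (is.null(sample_ids)) sample_ids <- rownames(band)
  if (is.null(locus_ids)) locus_ids <- colnames(band)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(band)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(band)))
  storage.mode(band) <- "integer"
  dimnames(band) <- list(as.character(sample_ids), as.character(locus_ids))
  validate_marker_matrix(band)
  class(band) <- c("marker_matrix", class(band))
  band
}

validate_marker_matrix <- function(band) {
  sample_ids <- rownames(band)
  locus_ids <- colnames(band)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  bad <- which(!(is.na(band) | band == 0L | band == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "band scores must be 0, 1 or missing; offending cell at sample '%s', locus '%s' (value %s)",
      sample_ids[bad[1, 1]], locus_ids[bad[1, 2]],
      band[bad[1, 1], bad[1, 2]]))
  }
  unscored <- rowSums(!is.na(band)) == 0
  if (any(unscored))
    stop("sample(s) with no scored locus: ",
         paste(sample_ids[unscored], collapse = ", "))
  invisible(band)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d samples x %d loci; %d missing cells (%.2f%%)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row of locus ids and one row per sample, first column the
#' sample id. The delimiter is sniffed (tab or comma) unless given.
#'
#' @param path file path.
#' @param missing string coding an unscored cell (default `"NA"`).
#' @param sep field delimiter; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, missing = "NA", sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character())
  sample_ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  band <- matrix(NA_integer_, nrow(cells), ncol(cells))
  band[cells == "0"] <- 0L
  band[cells == "1"] <- 1L
  ok <- matrix(cells %in% c("0", "1", missing), nrow(cells))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "cell outside {0, 1, %s} at sample '%s', locus '%s' (value '%s')",
      missing, sample_ids[bad[1, 1]], colnames(cells)[bad[1, 2]],
      cells[bad[1, 1], bad[1, 2]]))
  marker_matrix(band, sample_ids, colnames(cells))
}

#' Write a marker matrix to delimited text
#'
#' Inverse of [read_marker_matrix()]: `write` then `read` is the identity.
#'
#' @param x a [marker_matrix()].
#' @param path file path.
#' @param missing string to write for unscored cells.
#' @param sep field delimiter.
#' @export
write_marker_matrix <- function(x, path, missing = "NA", sep = "\t") {
  cells <- matrix(as.character(unclass(x)), nrow(x), ncol(x))
  cells[is.na(cells)] <- missing
  df <- data.frame(sample_id = rownames(x), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Export a marker matrix in a two-row-per-individual dominant layout
#'
#' Some Bayesian clustering tools consume dominant data as diploid genotypes
#' with one allele row unknown. Each sample is written as two rows: the first
#' carries the band score (1 = present, 0 = absent), the second the unknown
#' allele coded by `unknown`; missing scores are coded `missing` in both rows.
#' This coding convention is a documented choice of this exporter.
#'
#' @param x a [marker_matrix()].
#' @param path output path.
#' @param unknown code for the unobservable second allele (default `-9`).
#' @param missing code for unscored cells (default `-9`).
#' @export
export_dominant_diploid <- function(x, path, unknown = -9L, missing = -9L) {
  n <- nrow(x)
  out <- matrix(NA_integer_, 2L * n, ncol(x))
  first <- unclass(x)
  first[is.na(first)] <- missing
  out[seq(1, 2 * n, by = 2), ] <- first
  second <- matrix(unknown, n, ncol(x))
  second[is.na(unclass(x))] <- missing
  out[seq(2, 2 * n, by = 2), ] <- second
  df <- data.frame(sample_id = rep(rownames(x), each = 2), out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
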