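#' Read a sample metadata table
#'
#' Columns: `sample_id`, `population`, and optionally `region`,
#' `area` (`"native"` or `"introduced"`), `latitude`, `longitude` (decimal
#' degrees), `replicate_of` (the sample this row is a re-scoring of) and
#' `external_cluster` (a grouping label imported from an external clustering
#' tool). Unknown columns are kept.
#'
#' @param path CSV/TSV path.
#' @param sep delimiter; sniffed if `NULL`.
#' @return a validated `data.frame` of class `sample_frame`.
#' @export
read_sample_frame <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  sample_frame(df)
}

#' Validate a sample metadata frame
#'
#' @param df data.frame with at least `sample_id` and `population` columns.
#' @return `df` with class `sample_frame` prepended.
#' @export
sample_frame <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("sample_id", "population"))
    if (!col %in% names(df)) stop("sample frame lacks column '", col, "'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample frame: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(df$area)) {
    bad <- !(is.na(df$area) | df$area %in% c("native", "introduced"))
    if (any(bad))
      stop("area must be 'native' or 'introduced'; got: ",
           paste(unique(df$area[bad]), collapse = ", "))
  }
  if (!is.null(df$replicate_of)) {
    ref <- df$replicate_of[!is.na(df$replicate_of)]
    missing_ref <- setdiff(ref, df$sample_id)
    if (length(missing_ref) > 0)
      stop("replicate_of refers to unknown sample(s): ",
           paste(missing_ref, collapse = ", "))
  }
  if (!inherits(df, "sample_frame")) class(df) <- c("sample_frame", class(df))
  df
}

#' Drop replicate re-scorings from a marker matrix
#'
#' Returns the matrix restricted to primary samples (rows whose
#' `replicate_of` is unset in the metadata). Replicate rows only feed the
#' error-rate estimate; every other statistic runs on primary samples.
#'
#' @param x a [marker_matrix()].
#' @param samples a [sample_frame()].
#' @return a [marker_matrix()] of the primary rows.
#' @export
drop_replicates <- function(x, samples) {
  if (is.null(samples$replicate_of)) return(x)
  reps <- samples$sample_id[!is.na(samples$replicate_of)]
  keep <- setdiff(rownames(x), reps)
  marker_matrix(unclass(x)[keep, , drop = FALSE])
}

#' Read a crossing-records table
#'
#' One record per cross direction. Columns: `mother_population`,
#' `father_population`, optional `mother_sample`, `father_sample`, and the
#' counts `n_flowers`, `n_capsules`, `n_seeds`. Reciprocal records are kept
#' separately; crosses of a population with itself are accepted and flagged
#' in the `is_intra` column.
#'
#' @param path CSV/TSV path.
#' @param sep delimiter; sniffed if `NULL`.
#' @return a validated `data.frame` of class `cross_table`.
#' @export
read_crosses <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  cross_table(df)
}

#' Validate a crossing-records table
#'
#' @param df data.frame of crossing records (see [read_crosses()]).
#' @return `df` with `is_intra` added and class `cross_table`.
#' @export
cross_table <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("mother_population", "father_population",
              "n_flowers", "n_capsules", "n_seeds")
  for (col in needed)
    if (!col %in% names(df)) stop("cross table lacks column '", col, "'")
  if (nrow(df) > 0) {
    for (col in c("n_flowers", "n_capsules", "n_seeds")) {
      if (any(is.na(df[[col]])) || any(df[[col]] < 0))
        stop("negative or missing count in column '", col, "'")
    }
    if (any(df$n_flowers < 1)) stop("n_flowers must be >= 1 in every record")
  }
  df$is_intra <- df$mother_population == df$father_population
  if (!inherits(df, "cross_table")) class(df) <- c("cross_table", class(df))
  df
}

#' Read the reproductive-trait tables
#'
#' Three per-observation tables keyed by population and sample:
#' \describe{
#'   \item{flowers}{`population`, `sample_id`, `flower_class` (`"normal"` or
#'     a mutant subtype code), pollen aliquot counts `a1..a10`,
#'     `ovule_count`.}
#'   \item{capsules}{`population`, `sample_id`, `capsule_id`, `n_seeds`.}
#'   \item{seeds}{`population`, `capsule_id`, `width`, `length` (mm),
#'     `viability` in \{viable, abnormal, dead\}, `germinated` (0/1).}
#' }
#' Any subset may be supplied; absent tables are `NULL`.
#'
#' @param flowers,capsules,seeds file paths (CSV/TSV) or `NULL`.
#' @return a list of class `trait_tables`.
#' @export
read_traits <- function(flowers = NULL, capsules = NULL, seeds = NULL) {
  rd <- function(p) if (is.null(p)) NULL else
    utils::read.table(p, header = TRUE, sep = sniff_sep(p),
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", ""))
  trait_tables(flowers = rd(flowers), capsules = rd(capsules),
               seeds = rd(seeds))
}

#' Validate reproductive-trait tables
#'
#' @param flowers,capsules,seeds data.frames or `NULL` (see [read_traits()]).
#' @return a list of class `trait_tables`.
#' @export
trait_tables <- function(flowers = NULL, capsules = NULL, seeds = NULL) {
  if (!is.null(flowers)) {
    acols <- grep("^a([1-9]|10)$", names(flowers), value = TRUE)
    if (length(acols) > 0 && length(acols) != 10)
      stop("pollen aliquot columns must be exactly a1..a10; found ",
           length(acols))
  }
  if (!is.null(seeds)) {
    if (!is.null(seeds$width) &&
        any(!is.na(seeds$width) & seeds$width <= 0))
      stop("seed widths must be positive")
    if (!is.null(seeds$viability)) {
      bad <- !(is.na(seeds$viability) |
                 seeds$viability %in% c("viable", "abnormal", "dead"))
      if (any(bad))
        stop("viability class outside {viable, abnormal, dead}: ",
             paste(unique(seeds$viability[bad]), collapse = ", "))
    }
  }
  structure(list(flowers = flowers, capsules = capsules, seeds = seeds),
            class = "trait_tables")
}
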