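#' Construct an abundance table
#'
#' An abundance table holds non-negative taxon abundances for a set of
#' samples, together with per-taxon kingdom (`bacteria` or `fungi`) and
#' taxonomic rank annotations. It is stored as a tibble with one row per
#' taxon: the columns `taxon_id`, `kingdom` and `rank` are followed by one
#' numeric column per sample, mirroring the on-disk TSV layout. Whether the
#' values are raw abundances or per-kingdom relative fractions is tracked in
#' the `normalized` attribute.
#'
#' @param values Numeric matrix of abundances, taxa in rows and samples in
#'   columns, with dimnames giving taxon and sample identifiers. All values
#'   must be non-negative and finite.
#' @param kingdom Character vector, one of `"bacteria"` or `"fungi"` per
#'   taxon.
#' @param rank Character vector of taxonomic ranks per taxon (default
#'   `"genus"`).
#' @param normalized Logical; `TRUE` when the values are per-kingdom
#'   relative fractions (each kingdom summing to at most 1 within a sample).
#'
#' @return A tibble of class `abund_tbl`.
#' @export
#' @examples
#' m <- matrix(c(2, 1, 2, 3), 2, 2,
#'             dimnames = list(c("Bacillus", "Saccharomyces"), c("s1", "s2")))
#' abund_tbl(m, kingdom = c("bacteria", "fungi"))
abund_tbl <- function(values, kingdom, rank = "genus", normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (taxa x samples).")
  }
  taxa <- rownames(values)
  samples <- colnames(values)
  if (is.null(taxa) || is.null(samples)) {
    abort("`values` must carry taxon rownames and sample colnames.")
  }
  kingdom <- rep_len(kingdom, nrow(values))
  rank <- rep_len(rank, nrow(values))
  out <- tibble::tibble(taxon_id = taxa, kingdom = kingdom, rank = rank)
  out <- dplyr::bind_cols(out, tibble::as_tibble(values, .name_repair = "minimal"))
  new_abund_tbl(out, normalized = normalized)
}

new_abund_tbl <- function(x, normalized = FALSE) {
  x <- tibble::as_tibble(x)
  class(x) <- c("abund_tbl", setdiff(class(x), "abund_tbl"))
  attr(x, "normalized") <- isTRUE(normalized)
  validate_abund_tbl(x)
}

validate_abund_tbl <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  meta <- c("taxon_id", "kingdom", "rank")
  if (!all(meta %in% names(x))) {
    abort("An abundance table needs `taxon_id`, `kingdom` and `rank` columns.")
  }
  if (anyDuplicated(x$taxon_id)) {
    dup <- unique(x$taxon_id[duplicated(x$taxon_id)])
    abort(paste0("Duplicated taxon id(s): ", paste(dup, collapse = ", ")))
  }
  samples <- sample_ids(x)
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    abort(paste0("Duplicated sample id(s): ", paste(dup, collapse = ", ")))
  }
  bad_kingdom <- setdiff(unique(x$kingdom), c("bacteria", "fungi"))
  if (length(bad_kingdom)) {
    abort(paste0("Unknown kingdom label(s): ", paste(bad_kingdom, collapse = ", ")))
  }
  m <- abund_matrix(x)
  if (any(!is.finite(m))) abort("Abundances must be finite.")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative abundance at sample '%s', taxon '%s'.",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  if (is_normalized(x)) {
    for (k in unique(x$kingdom)) {
      tot <- rowSums(m[, x$kingdom == k, drop = FALSE])
      if (any(tot > 1 + 1e-9)) {
        abort(sprintf("Normalized table has kingdom '%s' sums above 1.", k))
      }
    }
  }
  x
}

#' Sample identifiers of an abundance table
#' @param x An `abund_tbl`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  setdiff(names(x), c("taxon_id", "kingdom", "rank"))
}

#' Extract the samples-by-taxa abundance matrix
#'
#' @param x An `abund_tbl`.
#' @param kingdom Optional kingdom filter (`"bacteria"` or `"fungi"`).
#' @return Numeric matrix with samples in rows, taxa in columns.
#' @export
abund_matrix <- function(x, kingdom = NULL) {
  keep <- if (is.null(kingdom)) rep(TRUE, nrow(x)) else x$kingdom %in% kingdom
  samples <- sample_ids(x)
  m <- t(as.matrix(x[keep, samples, drop = FALSE]))
  dimnames(m) <- list(samples, x$taxon_id[keep])
  storage.mode(m) <- "double"
  m
}

#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Read an abundance table from TSV
#'
#' Expects taxa in rows and samples in columns: the first column holds taxon
#' identifiers, optional reserved columns `kingdom` and `rank` carry the
#' annotations, and all remaining columns are numeric sample abundances.
#' Decimal separator is `"."` regardless of locale.
#'
#' @param path Path to a tab-separated file.
#' @param normalized Logical; mark the table as already normalized.
#' @return An [abund_tbl].
#' @export
read_abundance_tsv <- function(path, normalized = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  if (ncol(raw) < 2) abort("Abundance TSV needs a taxon column plus sample columns.")
  names(raw)[1] <- "taxon_id"
  if (!"kingdom" %in% names(raw)) raw$kingdom <- "fungi"
  if (!"rank" %in% names(raw)) raw$rank <- "genus"
  samples <- setdiff(names(raw), c("taxon_id", "kingdom", "rank"))
  for (s in samples) {
    v <- raw[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(sprintf("Non-numeric value in column '%s', row %d.", s,
                    if (length(bad)) bad[1] else 1L))
    }
    if (anyNA(v)) abort(sprintf("Missing value in column '%s', row %d.", s, which(is.na(v))[1]))
    if (any(v < 0)) {
      abort(sprintf("Negative abundance at row %d (taxon '%s'), column '%s'.",
                    which(v < 0)[1], raw$taxon_id[which(v < 0)[1]], s))
    }
  }
  new_abund_tbl(raw[, c("taxon_id", "kingdom", "rank", samples)], normalized = normalized)
}

#' Write an abundance table to TSV
#'
#' @param x An [abund_tbl].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' The file must contain a `sample_id` column and a `group` column; clinical
#' covariates such as `age`, `sex`, `total_ige` (IU/mL) and allergen-specific
#' IgE columns (`sige_*`, kU_A/L) are carried through unchanged.
#'
#' @param path Path to a tab-separated file.
#' @param abundance Optional [abund_tbl] to validate sample ids against.
#' @return A tibble.
#' @export
read_metadata_tsv <- function(path, abundance = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_metadata(md, abundance)
}

validate_metadata <- function(md, abundance = NULL) {
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort("Metadata needs `sample_id` and `group` columns.")
  }
  if (anyDuplicated(md$sample_id)) abort("Duplicated sample_id in metadata.")
  if ("total_ige" %in% names(md) && any(md$total_ige < 0, na.rm = TRUE)) {
    abort("total_ige must be non-negative.")
  }
  if (!is.null(abundance)) {
    missing <- setdiff(md$sample_id, sample_ids(abundance))
    if (length(missing)) {
      abort(paste0("Metadata samples absent from abundance table: ",
                   paste(missing, collapse = ", ")))
    }
  }
  tibble::as_tibble(md)
}

#' Convert abundances to per-kingdom relative fractions
#'
#' Within each sample, abundances of each kingdom are divided by that
#' kingdom's sample total (total-sum scaling), so bacterial and fungal
#' fractions each sum to 1 within a sample. This mirrors kingdom-specific
#' relative abundance reporting when both communities are profiled from one
#' metagenome. A kingdom with an all-zero sample total yields zero fractions
#' for that sample, not `NaN`. With `joint = TRUE` a single total over all
#' taxa is used instead.
#'
#' @param x An [abund_tbl] that has not been normalized yet.
#' @param joint Normalize over all taxa jointly rather than per kingdom.
#' @return A normalized [abund_tbl].
#' @export
to_relative_abundance <- function(x, joint = FALSE) {
  validate_abund_tbl(x)
  if (is_normalized(x)) abort("Table is already normalized.")
  samples <- sample_ids(x)
  m <- as.matrix(x[, samples, drop = FALSE])  # taxa x samples
  groups <- if (joint) rep("all", nrow(x)) else x$kingdom
  for (k in unique(groups)) {
    rows <- groups == k
    tot <- colSums(m[rows, , drop = FALSE])
    scale <- ifelse(tot > 0, 1 / tot, 0)
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2, scale, `*`)
  }
  out <- x
  out[, samples] <- tibble::as_tibble(m, .name_repair = "minimal")
  attr(out, "normalized") <- TRUE
  validate_abund_tbl(out)
}

#' Filter taxa by prevalence
#'
#' Retains taxa with non-zero abundance in at least `min_prev` of samples.
#' Row order is preserved; `min_prev = 0` keeps everything. Applied before
#' correlation network construction so that correlations are not driven by
#' taxa observed in a handful of samples.
#'
#' @param x An [abund_tbl].
#' @param min_prev Minimum prevalence as a fraction in `[0, 1]`
#'   (default 0.25).
#' @return A filtered [abund_tbl]; may have zero rows.
#' @export
prevalence_filter <- function(x, min_prev = 0.25) {
  validate_abund_tbl(x)
  if (!is.numeric(min_prev) || min_prev < 0 || min_prev > 1) {
    abort("`min_prev` must be a fraction in [0, 1].")
  }
  samples <- sample_ids(x)
  m <- as.matrix(x[, samples, drop = FALSE])
  prev <- rowMeans(m > 0)
  out <- x[prev >= min_prev, , drop = FALSE]
  new_abund_tbl(out, normalized = is_normalized(x))
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table: %d taxa x %d samples (%s)\n",
              nrow(x), length(sample_ids(x)),
              if (is_normalized(x)) "relative fractions" else "raw abundances"))
  NextMethod()
}
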