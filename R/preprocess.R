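# Rank-based inverse-normal scaling and cohort harmonization -------------------

#' Rank-based inverse-normal transformation
#'
#' Maps a numeric vector to standard-normal quantiles through its ranks: a
#' value with (average, tie-shared) rank r among n non-missing values becomes
#' `qnorm((r - offset) / (n - 2 * offset + 1))`. The default `offset = 3/8`
#' is the Blom convention, `(r - 3/8) / (n + 1/4)`, the common choice for
#' omics trait association scans. Ties receive the same transformed value;
#' missing entries stay missing.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @param offset Rank offset in (0, 0.5]; `3/8` (Blom) by default.
#' @return Numeric vector of the same length, transformed where non-missing.
#' @examples
#' inverse_normal(c(10, 20, 30))  # middle value maps to exactly 0
#' @export
inverse_normal <- function(values, offset = 3 / 8) {
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3L) {
    stop("insufficient data: need at least 3 non-missing values, got ", n,
      call. = FALSE)
  }
  if (length(unique(values[ok])) == 1L) {
    stop("all-ties: vector is constant over its non-missing values", call. = FALSE)
  }
  r <- rank(values, na.last = "keep", ties.method = "average")
  out <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  names(out) <- names(values)
  out
}

#' Inverse-normal scale every column of a feature matrix
#'
#' Applies [inverse_normal()] per feature (column). Constant columns and
#' columns with fewer than 3 non-missing values cannot be scaled; they are
#' dropped from the result and listed in the `"excluded"` attribute.
#'
#' @param mat Numeric matrix, samples x features.
#' @param offset Rank offset, see [inverse_normal()].
#' @return Transformed matrix (possibly fewer columns) with attributes
#'   `"excluded"` (character vector of dropped feature ids) and
#'   `"n_nonmissing"` (per kept feature).
#' @export
inverse_normal_matrix <- function(mat, offset = 3 / 8) {
  stopifnot(is.matrix(mat))
  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    res <- tryCatch(inverse_normal(mat[, j], offset = offset), error = function(e) NULL)
    if (!is.null(res)) {
      out[, j] <- res
      keep[j] <- TRUE
    }
  }
  excluded <- colnames(mat)[!keep]
  out <- out[, keep, drop = FALSE]
  attr(out, "excluded") <- excluded
  attr(out, "n_nonmissing") <- colSums(!is.na(out))
  out
}

normalize_feature_id <- function(id) {
  tolower(gsub("\\s+", "", trimws(id)))
}

#' Restrict discovery and replication matrices to their common features
#'
#' Feature ids are compared after trimming/collapsing whitespace and case
#' folding, so cosmetic id variants across cohorts still match; the
#' discovery spelling and column order are kept. Features absent from either
#' cohort are dropped and listed in the report.
#'
#' @param discovery,replication Numeric matrices (samples x features).
#' @return A list with elements `discovery`, `replication` (common columns,
#'   discovery order) and `report` (list with `n_common`,
#'   `dropped_discovery`, `dropped_replication`, `renamed_replication`).
#' @export
align_cohorts <- function(discovery, replication) {
  stopifnot(is.matrix(discovery), is.matrix(replication))
  d_ids <- colnames(discovery)
  r_ids <- colnames(replication)
  if (is.null(d_ids) || is.null(r_ids)) {
    stop("both matrices must have feature (column) names", call. = FALSE)
  }
  d_key <- normalize_feature_id(d_ids)
  r_key <- normalize_feature_id(r_ids)
  if (anyDuplicated(d_key) || anyDuplicated(r_key)) {
    stop("feature ids are not unique after normalization", call. = FALSE)
  }
  common <- d_key[d_key %in% r_key]
  if (length(common) == 0L) {
    stop("alignment error: no features shared between cohorts", call. = FALSE)
  }
  d_idx <- match(common, d_key)
  r_idx <- match(common, r_key)
  out_disc <- discovery[, d_idx, drop = FALSE]
  out_rep <- replication[, r_idx, drop = FALSE]
  renamed <- r_ids[r_idx] != d_ids[d_idx]
  colnames(out_rep) <- d_ids[d_idx]  # discovery spelling wins
  list(
    discovery = out_disc,
    replication = out_rep,
    report = list(
      n_common = length(common),
      dropped_discovery = d_ids[!d_key %in% r_key],
      dropped_replication = r_ids[!r_key %in% d_key],
      renamed_replication = r_ids[r_idx][renamed]
    )
  )
}
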