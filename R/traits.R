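# Trait derivation -------------------------------------------------------------
#
# The chromatogram is integrated into 36 peak areas per sample; everything
# downstream works on the compositional representation "percent of total
# integrated area". Derived traits are linear (group percents), projective
# (sub-fraction percents, incl. the neutral GPn subprofile) or rational
# (ratios of two traits) functions of the peak percentages, so the whole trait
# vector is invariant to rescaling of the raw areas.

#' Normalize raw peak areas to percent of total integrated area
#'
#' @param raw_areas Named non-negative numeric vector of integrated peak
#'   areas, one entry per annotated peak (names are peak ids GP1-GP36 for the
#'   shipped annotation).
#' @param annotations A `peak_annotation` giving the expected peak set.
#' @return Named numeric vector in the annotation's peak order, summing
#'   to 100.
#' @examples
#' areas <- stats::setNames(rep(1, 36), paste0("GP", 1:36))
#' normalize_peaks(areas)[1]  # 100/36
#' @export
normalize_peaks <- function(raw_areas, annotations = builtin_peak_annotations()) {
  if (is.null(names(raw_areas))) {
    stop("`raw_areas` must be named by peak id", call. = FALSE)
  }
  missing_peaks <- setdiff(annotations$peak_id, names(raw_areas))
  if (length(missing_peaks) > 0L) {
    stop("missing peak(s): ", paste(missing_peaks, collapse = ", "), call. = FALSE)
  }
  x <- raw_areas[annotations$peak_id]
  if (any(is.na(x))) {
    stop("missing (NA) peak areas are not normalizable", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("negative peak area(s): ", paste(names(x)[x < 0], collapse = ", "), call. = FALSE)
  }
  total <- sum(x)
  if (total <= 0) {
    stop("degenerate profile: all peak areas are zero", call. = FALSE)
  }
  100 * x / total
}

#' Normalize a sample-by-peak area matrix row-wise to percentages
#'
#' Matrix version of [normalize_peaks()]: each row (sample) is expressed as
#' percent of its total integrated area.
#'
#' @param areas Numeric matrix, samples in rows, peak ids as column names.
#' @param annotations A `peak_annotation`.
#' @return Matrix of the same shape (columns in annotation order), rows
#'   summing to 100.
#' @export
normalize_peak_matrix <- function(areas, annotations = builtin_peak_annotations()) {
  stopifnot(is.matrix(areas))
  missing_peaks <- setdiff(annotations$peak_id, colnames(areas))
  if (length(missing_peaks) > 0L) {
    stop("missing peak column(s): ", paste(missing_peaks, collapse = ", "), call. = FALSE)
  }
  x <- areas[, annotations$peak_id, drop = FALSE]
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative peak area(s) present", call. = FALSE)
  }
  totals <- rowSums(x)
  if (any(!is.na(totals) & totals <= 0)) {
    stop(
      "degenerate profile(s) with zero total area: ",
      paste(rownames(x)[!is.na(totals) & totals <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  sweep(x, 1L, totals, "/") * 100
}

#' Percentages within the neutral peak subset (GPn)
#'
#' Re-normalizes a profile over the peaks whose dominant structure is
#' unsialylated, the "total neutral plasma glycans" denominator used by GPn
#' traits such as "M9 in total neutral plasma glycans".
#'
#' @param profile Named numeric vector of peak percentages (of total area).
#' @param annotations A `peak_annotation`.
#' @return Named numeric vector over the neutral peaks, summing to 100.
#' @export
neutral_subprofile <- function(profile, annotations = builtin_peak_annotations()) {
  neutral <- neutral_peaks(annotations)
  if (length(neutral) == 0L) {
    stop("annotation table defines no neutral peaks", call. = FALSE)
  }
  missing_peaks <- setdiff(neutral, names(profile))
  if (length(missing_peaks) > 0L) {
    stop("missing neutral peak(s): ", paste(missing_peaks, collapse = ", "), call. = FALSE)
  }
  x <- profile[neutral]
  total <- sum(x)
  if (is.na(total) || total <= 0) {
    stop("degenerate profile: neutral peak total is zero", call. = FALSE)
  }
  100 * x / total
}

# Resolve a trait's numerator/denominator peak sets against an annotation
# table. For sub-fraction traits the numerator is evaluated *within* the
# denominator set, so catalog predicates only need the distinguishing clause.
resolve_trait_peaks <- function(trait, annotations) {
  den_peaks <- switch(trait$denominator,
    total = annotations$peak_id,
    neutral_total = neutral_peaks(annotations),
    predicate = match_peaks(annotations, trait$denominator_predicate),
    stop("unknown denominator kind: ", trait$denominator, call. = FALSE)
  )
  num_peaks <- if (!is.null(trait$peaks)) {
    trait$peaks
  } else if (!is.null(trait$numerator_predicate)) {
    match_peaks(annotations, trait$numerator_predicate)
  } else {
    character(0)
  }
  list(numerator = intersect(num_peaks, den_peaks), denominator = den_peaks)
}

#' Evaluate one trait for a single glycome profile
#'
#' @param defn A `trait_definition` (one element of a catalog's `traits`).
#' @param profile Named numeric vector of peak percentages summing to 100.
#' @param annotations A `peak_annotation`.
#' @param catalog The enclosing `trait_catalog`; required for ratio traits so
#'   their component traits can be resolved.
#' @return The trait value: a percent on the 0-100 scale for primary, group
#'   and sub-fraction traits, a dimensionless ratio for ratio traits. A zero
#'   denominator yields `NA` (the sample is dropped pairwise downstream),
#'   never an error.
#' @export
evaluate_trait <- function(defn, profile, annotations = builtin_peak_annotations(),
                           catalog = NULL) {
  stopifnot(inherits(defn, "trait_definition"))
  if (defn$kind == "ratio") {
    if (is.null(catalog)) {
      stop("ratio trait ", defn$trait_id, " needs the enclosing catalog", call. = FALSE)
    }
    num <- evaluate_trait(catalog$traits[[defn$num_trait]], profile, annotations, catalog)
    den <- evaluate_trait(catalog$traits[[defn$den_trait]], profile, annotations, catalog)
    if (is.na(den) || is.na(num) || den == 0) return(NA_real_)
    return(num / den)
  }
  sets <- resolve_trait_peaks(defn, annotations)
  num_sum <- sum(profile[sets$numerator])
  if (defn$kind %in% c("primary", "group_percent")) {
    if (defn$kind == "primary") {
      return(unname(profile[defn$peaks]))
    }
    return(unname(num_sum))
  }
  den_sum <- sum(profile[sets$denominator])
  if (is.na(den_sum) || den_sum == 0) return(NA_real_)
  unname(100 * num_sum / den_sum)
}

#' Derive the full trait matrix for a set of glycome profiles
#'
#' Evaluates every catalog trait on every sample. Group membership of a peak
#' is decided by its dominant structure; sub-fraction numerators are counted
#' within their denominator set; ratio traits are computed from the already
#' derived component columns. Zero denominators propagate as `NA`.
#'
#' @param profiles Numeric matrix of peak percentages (samples x peaks,
#'   column names = peak ids, rows summing to 100), e.g. from
#'   [normalize_peak_matrix()]. A single named vector is treated as one
#'   sample.
#' @param catalog A `trait_catalog` (default: the shipped 113-trait catalog).
#' @param annotations A `peak_annotation`.
#' @return Numeric matrix, samples x traits, column names = trait ids, with
#'   attribute `"kind"` giving each column's trait kind.
#' @examples
#' prof <- normalize_peaks(stats::setNames(runif(36, 1, 5), paste0("GP", 1:36)))
#' tr <- derive_all(prof)
#' tr[, c("PGP93", "PGP97")]
#' @export
derive_all <- function(profiles, catalog = builtin_catalog(),
                       annotations = builtin_peak_annotations()) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1L,
      dimnames = list("sample1", names(profiles)))
  }
  if (nrow(profiles) == 0L) {
    stop("empty profile set", call. = FALSE)
  }
  missing_peaks <- setdiff(annotations$peak_id, colnames(profiles))
  if (length(missing_peaks) > 0L) {
    stop("missing peak column(s): ", paste(missing_peaks, collapse = ", "), call. = FALSE)
  }
  P <- profiles[, annotations$peak_id, drop = FALSE]
  traits <- catalog$traits
  ids <- names(traits)
  out <- matrix(NA_real_, nrow = nrow(P), ncol = length(traits),
    dimnames = list(rownames(P), ids))

  # Non-ratio traits first (ratio components are guaranteed non-ratio by
  # validate_catalog), then ratios from the derived columns.
  for (t in traits) {
    if (t$kind == "ratio") next
    sets <- resolve_trait_peaks(t, annotations)
    num_sum <- if (length(sets$numerator) > 0L) {
      rowSums(P[, sets$numerator, drop = FALSE])
    } else {
      rep(0, nrow(P))
    }
    if (t$kind %in% c("primary", "group_percent")) {
      out[, t$trait_id] <- num_sum
    } else {
      den_sum <- rowSums(P[, sets$denominator, drop = FALSE])
      val <- 100 * num_sum / den_sum
      val[!is.na(den_sum) & den_sum == 0] <- NA_real_
      out[, t$trait_id] <- val
    }
  }
  for (t in traits) {
    if (t$kind != "ratio") next
    num <- out[, t$num_trait]
    den <- out[, t$den_trait]
    val <- num / den
    val[!is.na(den) & den == 0] <- NA_real_
    out[, t$trait_id] <- val
  }
  kinds <- vapply(traits, function(t) t$kind, "")
  attr(out, "kind") <- kinds
  out
}
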