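# Discovery-replication association scan ---------------------------------------
#
# The scan correlates every protein with every glycan trait in the discovery
# cohort (Pearson on inverse-normal-scaled levels; with a single predictor and
# scaled variables this is equivalent to the linear-model t-test, so slope and
# intercept are also reported), applies a Bonferroni cut over the full pair
# grid, and then requires nominal significance (p < 0.05) with the same effect
# direction in an independent replication cohort.

#' Pearson correlation test on pairwise-complete observations
#'
#' Computes the sample Pearson correlation r over the pairwise-complete
#' observations and its two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom
#' (`|r| = 1` gives p = 0). The least-squares slope and intercept of y on x
#' are reported alongside.
#'
#' @param x,y Numeric vectors of equal length; `NA`s are dropped pairwise.
#' @return List with elements `r`, `p`, `n`, `slope`, `intercept`.
#' @examples
#' pearson_test(c(1, 2, 3), c(2, 4, 6))  # r = 1, p = 0
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    stop("insufficient data: need at least 3 pairwise-complete pairs, got ", n,
      call. = FALSE)
  }
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input on the complete pairs", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  slope <- r * stats::sd(y) / stats::sd(x)
  list(r = r, p = p, n = n, slope = slope,
    intercept = mean(y) - slope * mean(x))
}

# Two-sided p for a Pearson r at sample size n via the t transform.
pearson_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  p <- ifelse(r2 >= 1, 0, {
    tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  })
  as.numeric(p)
}

#' Bonferroni significance threshold for the all-pairs scan
#'
#' The family-wise level `alpha` divided by the number of tested pairs,
#' `n_proteins * n_glycans`. For the 1116-protein by 113-trait grid at
#' alpha = 0.05 this is 3.96e-7.
#'
#' @param n_proteins,n_glycans Positive counts of features on each layer.
#' @param alpha Family-wise error level in (0, 1).
#' @return The per-test threshold `alpha / (n_proteins * n_glycans)`.
#' @export
bonferroni_threshold <- function(n_proteins, n_glycans, alpha = 0.05) {
  if (n_proteins < 1 || n_glycans < 1) {
    stop("feature counts must be at least 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  alpha / (n_proteins * n_glycans)
}

# All-pairs r, p and n between the columns of two sample-aligned matrices.
# Fast path (no missing data) uses one cross-product; otherwise pairwise
# complete observations, so n may differ across pairs.
cor_grid <- function(X, Y) {
  n_all <- nrow(X)
  if (!anyNA(X) && !anyNA(Y)) {
    Xs <- scale(X)
    Ys <- scale(Y)
    R <- crossprod(Xs, Ys) / (n_all - 1)
    N <- matrix(n_all, ncol(X), ncol(Y))
  } else {
    R <- stats::cor(X, Y, use = "pairwise.complete.obs")
    N <- crossprod(!is.na(X), !is.na(Y))
  }
  R <- pmin(pmax(R, -1), 1)
  P <- matrix(pearson_p(as.vector(R), as.vector(N)), nrow(R), ncol(R))
  dimnames(P) <- dimnames(R)
  dimnames(N) <- dimnames(R)
  list(r = R, p = P, n = N)
}

align_samples <- function(proteins, glycans) {
  shared <- intersect(rownames(proteins), rownames(glycans))
  if (length(shared) == 0L) {
    stop("alignment error: no shared sample ids between the two matrices",
      call. = FALSE)
  }
  list(proteins = proteins[shared, , drop = FALSE],
    glycans = glycans[shared, , drop = FALSE])
}

#' All-pairs discovery association scan
#'
#' Correlates every protein with every glycan trait over the shared samples
#' of the two matrices and labels each pair `discovered` when its p-value
#' falls below the Bonferroni threshold `alpha / (n_proteins * n_glycans)`
#' (strict inequality), `not_significant` otherwise.
#'
#' @param proteins,glycans Numeric matrices (samples x features, sample ids
#'   as row names), already inverse-normal scaled; see
#'   [inverse_normal_matrix()].
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return An `association_records` data frame in deterministic glycan-major
#'   order with columns `glycan_id`, `protein_id`, `r_disc`, `p_disc`,
#'   `n_disc`, `status`, and attributes `threshold`, `alpha`,
#'   `n_proteins`, `n_glycans`.
#' @export
discovery_scan <- function(proteins, glycans, alpha = 0.05) {
  al <- align_samples(proteins, glycans)
  g <- cor_grid(al$glycans, al$proteins)  # glycans in rows => glycan-major
  threshold <- bonferroni_threshold(ncol(proteins), ncol(glycans), alpha)
  rec <- data.frame(
    glycan_id = rep(colnames(al$glycans), each = ncol(al$proteins)),
    protein_id = rep(colnames(al$proteins), times = ncol(al$glycans)),
    r_disc = as.vector(t(g$r)),
    p_disc = as.vector(t(g$p)),
    n_disc = as.vector(t(g$n)),
    stringsAsFactors = FALSE
  )
  rec$status <- ifelse(rec$p_disc < threshold, "discovered", "not_significant")
  attr(rec, "threshold") <- threshold
  attr(rec, "alpha") <- alpha
  attr(rec, "n_proteins") <- ncol(proteins)
  attr(rec, "n_glycans") <- ncol(glycans)
  class(rec) <- c("association_records", "data.frame")
  rec
}

#' Replicate discovered associations in a second cohort
#'
#' For every `discovered` record, recomputes the Pearson statistics on the
#' replication cohort and assigns the final status: `replicated` when
#' p < `p_cutoff` (strict) with the discovery effect direction, `conflicting`
#' when p < `p_cutoff` with the opposite direction, `not_replicated`
#' otherwise (including pairs untestable in the replication cohort, flagged
#' in `rep_reason`). `not_significant` records are never upgraded.
#'
#' @param records An `association_records` data frame from
#'   [discovery_scan()].
#' @param proteins,glycans Replication-cohort matrices, inverse-normal scaled
#'   and feature-aligned to the discovery cohort (see [align_cohorts()]).
#' @param p_cutoff Nominal replication significance level; 0.05 by default.
#' @return The records with added columns `r_rep`, `p_rep`, `n_rep`,
#'   `rep_reason` and updated `status`.
#' @export
replicate_associations <- function(records, proteins, glycans, p_cutoff = 0.05) {
  stopifnot(inherits(records, "association_records"))
  records$r_rep <- NA_real_
  records$p_rep <- NA_real_
  records$n_rep <- NA_integer_
  records$rep_reason <- NA_character_
  disc <- which(records$status == "discovered")
  if (length(disc) == 0L) {
    return(records)
  }
  al <- align_samples(proteins, glycans)
  for (i in disc) {
    gl <- records$glycan_id[i]
    pr <- records$protein_id[i]
    if (!(gl %in% colnames(al$glycans)) || !(pr %in% colnames(al$proteins))) {
      records$status[i] <- "not_replicated"
      records$rep_reason[i] <- "feature_missing_in_replication"
      next
    }
    res <- tryCatch(
      pearson_test(al$proteins[, pr], al$glycans[, gl]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      records$status[i] <- "not_replicated"
      records$rep_reason[i] <- "untestable"
      next
    }
    records$r_rep[i] <- res$r
    records$p_rep[i] <- res$p
    records$n_rep[i] <- res$n
    if (res$p < p_cutoff) {
      if (res$r == 0) {
        # sign undefined: cannot display a consistent trend
        records$status[i] <- "not_replicated"
        records$rep_reason[i] <- "zero_effect"
      } else if (sign(res$r) == sign(records$r_disc[i])) {
        records$status[i] <- "replicated"
      } else {
        records$status[i] <- "conflicting"
      }
    } else {
      records$status[i] <- "not_replicated"
    }
  }
  attr(records, "p_cutoff") <- p_cutoff
  records
}

#' Assemble the signed-r-squared association matrix
#'
#' Arranges the replicated associations into a glycan-by-protein matrix whose
#' entries are the discovery correlation squared, carrying the sign of the
#' correlation (`sign(r_disc) * r_disc^2`). Rows and columns are restricted
#' to glycans/proteins with at least one replicated association;
#' non-replicated cells are `NA`.
#'
#' @param records Records processed by [replicate_associations()].
#' @return Numeric matrix (glycans x proteins) of signed r-squared entries;
#'   a 0 x 0 matrix with a warning when nothing replicated.
#' @export
association_matrix <- function(records) {
  stopifnot(inherits(records, "association_records"))
  rep_rec <- records[records$status == "replicated", , drop = FALSE]
  if (nrow(rep_rec) == 0L) {
    warning("no replicated associations; returning an empty matrix", call. = FALSE)
    return(matrix(numeric(0), 0L, 0L))
  }
  glycans <- unique(rep_rec$glycan_id)
  proteins <- unique(rep_rec$protein_id)
  out <- matrix(NA_real_, length(glycans), length(proteins),
    dimnames = list(glycans, proteins))
  out[cbind(rep_rec$glycan_id, rep_rec$protein_id)] <-
    sign(rep_rec$r_disc) * rep_rec$r_disc^2
  out
}

#' Cross-cohort effect-size consistency report
#'
#' Tabulates the discovery and replication correlation coefficients per pair,
#' sorted by decreasing discovery effect size, and computes the fraction of
#' pairs whose effects point the same way in both cohorts. Running the scan
#' with the cohorts' roles swapped (replication-as-discovery) produces
#' records this report consumes unchanged.
#'
#' @param records Records carrying both cohorts' statistics (rows without a
#'   replication estimate are skipped).
#' @return Data frame with columns `glycan_id`, `protein_id`, `r_disc`,
#'   `r_rep`, `concordant`, sorted by `|r_disc|` descending, with attribute
#'   `"concordance"` (a pair with `r_rep = 0` counts as non-concordant).
#' @export
consistency_report <- function(records) {
  df <- as.data.frame(records)[, c("glycan_id", "protein_id", "r_disc", "r_rep")]
  df <- df[!is.na(df$r_rep), , drop = FALSE]
  df$concordant <- sign(df$r_disc) == sign(df$r_rep) & df$r_rep != 0
  df <- df[order(-abs(df$r_disc)), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "concordance") <- if (nrow(df) > 0L) mean(df$concordant) else NA_real_
  df
}

#' Count association records by status
#'
#' @param records An `association_records` data frame.
#' @return Named integer vector over the five status labels.
#' @export
status_counts <- function(records) {
  levels <- c("not_significant", "discovered", "replicated", "conflicting",
    "not_replicated")
  counts <- table(factor(records$status, levels = levels))
  stats::setNames(as.integer(counts), levels)
}
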