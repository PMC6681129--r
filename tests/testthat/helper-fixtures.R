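# Shared fixtures and the independent brute-force trait oracle.

peak_ids <- function() paste0("GP", 1:36)

# A profile with all mass on the given peaks (equal split), as percentages.
point_profile <- function(peaks) {
  prof <- stats::setNames(rep(0, 36), peak_ids())
  prof[peaks] <- 100 / length(peaks)
  prof
}

random_profiles <- function(n, seed = 1, allow_zero = FALSE) {
  set.seed(seed)
  raw <- matrix(stats::rgamma(n * 36, shape = if (allow_zero) 0.15 else 1.5),
    n, 36, dimnames = list(sprintf("S%04d", seq_len(n)), peak_ids()))
  sweep(raw, 1, rowSums(raw), "/") * 100
}

# --- Brute-force trait oracle -------------------------------------------------
# Re-resolves trait membership and recomputes every value with plain loops,
# re-testing each predicate clause field by field, independently of the
# catalog evaluation engine (resolve_trait_peaks / derive_all).

oracle_clause_holds <- function(feature_list, clause) {
  actual <- feature_list[[clause$field]]
  v <- clause$value
  if (clause$op == "eq") return(isTRUE(all.equal(actual, v)) || identical(actual, v))
  if (clause$op == "ne") return(!(isTRUE(all.equal(actual, v)) || identical(actual, v)))
  if (clause$op == "ge") return(actual >= v)
  if (clause$op == "le") return(actual <= v)
  if (clause$op == "gt") return(actual > v)
  if (clause$op == "lt") return(actual < v)
  stop("oracle: unknown op ", clause$op)
}

oracle_peak_features <- function(annotations) {
  lapply(seq_len(nrow(annotations)), function(i) {
    lab <- strsplit(annotations$structure_labels[i], " + ", fixed = TRUE)[[1]]
    dom <- parse_structure(trimws(lab[annotations$dominant_index[i]]))
    dom[c("family", "antennae", "core_fucose", "bisecting_glcnac",
      "antennary_fucoses", "galactoses", "galactose_arm", "sialic_acids",
      "mannoses")]
  })
}

oracle_matching_peaks <- function(features, peak_names, predicate) {
  if (is.null(predicate)) return(character(0))
  hit <- vapply(features, function(f) {
    for (cl in predicate) {
      if (!oracle_clause_holds(f, cl)) return(FALSE)
    }
    TRUE
  }, logical(1))
  peak_names[hit]
}

# Trait values for one profile (named percent vector), brute force.
oracle_trait_values <- function(profile, catalog, annotations) {
  features <- oracle_peak_features(annotations)
  pk <- annotations$peak_id
  neutral <- pk[vapply(features, function(f) f$sialic_acids == 0, TRUE)]
  vals <- stats::setNames(rep(NA_real_, length(catalog$traits)), names(catalog$traits))
  for (t in catalog$traits) {
    if (t$kind == "ratio") next
    den_set <- if (t$denominator == "total") {
      pk
    } else if (t$denominator == "neutral_total") {
      neutral
    } else {
      oracle_matching_peaks(features, pk, t$denominator_predicate)
    }
    num_set <- if (!is.null(t$peaks)) t$peaks else {
      oracle_matching_peaks(features, pk, t$numerator_predicate)
    }
    num_set <- num_set[num_set %in% den_set]
    num_sum <- 0
    for (p in num_set) num_sum <- num_sum + profile[[p]]
    if (t$kind %in% c("primary", "group_percent")) {
      vals[t$trait_id] <- num_sum
    } else {
      den_sum <- 0
      for (p in den_set) den_sum <- den_sum + profile[[p]]
      vals[t$trait_id] <- if (den_sum == 0) NA_real_ else 100 * num_sum / den_sum
    }
  }
  for (t in catalog$traits) {
    if (t$kind != "ratio") next
    den <- vals[[t$den_trait]]
    num <- vals[[t$num_trait]]
    vals[t$trait_id] <- if (is.na(den) || den == 0 || is.na(num)) NA_real_ else num / den
  }
  vals
}

# Build an association_records data frame by hand (for replication-rule and
# consistency-report fixtures).
make_records <- function(df, threshold = 1e-6) {
  attr(df, "threshold") <- threshold
  class(df) <- c("association_records", "data.frame")
  df
}
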