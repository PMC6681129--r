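# File I/O and the end-to-end pipeline ----------------------------------------
#
# All tabular interchange is TSV (trait names contain commas) with a header
# row whose first column is sample_id; empty cells are missing values.

#' Read a sample-by-feature matrix from TSV
#'
#' @param path Path to a TSV file with a header row; first column
#'   `sample_id`, remaining columns numeric features. Empty cells parse as
#'   missing.
#' @param kind One of `"protein"`, `"peak"`, `"trait"`; stored as an
#'   attribute and, for `"peak"`, checked against the shipped peak set.
#' @return Numeric matrix with sample ids as row names and attribute
#'   `"kind"`.
#' @export
read_matrix <- function(path, kind = c("protein", "peak", "trait")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("parse error in ", path, ": need a header row and at least one sample",
      call. = FALSE)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 2L || header[1L] != "sample_id") {
    stop("parse error in ", path, " line 1: first column must be 'sample_id'",
      call. = FALSE)
  }
  ncol_expected <- length(header)
  body <- cells[-1L]
  # trailing empty cells are dropped by strsplit; pad before the ragged check
  body <- lapply(body, function(row) {
    if (length(row) < ncol_expected) c(row, rep("", ncol_expected - length(row))) else row
  })
  bad <- which(lengths(body) != ncol_expected)
  if (length(bad) > 0L) {
    stop("parse error in ", path, " line ", bad[1L] + 1L, ": expected ",
      ncol_expected, " fields, found ", lengths(body)[bad[1L]], call. = FALSE)
  }
  sample_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id(s) in ", path, ": ", paste(dup, collapse = ", "),
      call. = FALSE)
  }
  values <- matrix(NA_real_, length(body), ncol_expected - 1L,
    dimnames = list(sample_ids, header[-1L]))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    empty <- !nzchar(trimws(raw))
    num <- suppressWarnings(as.numeric(raw))
    bad_cell <- which(!empty & is.na(num))
    if (length(bad_cell) > 0L) {
      stop("parse error in ", path, " line ", i + 1L, ": non-numeric value '",
        raw[bad_cell[1L]], "' in column ", header[bad_cell[1L] + 1L],
        call. = FALSE)
    }
    num[empty] <- NA_real_
    values[i, ] <- num
  }
  if (kind == "peak") {
    expected <- builtin_peak_annotations()$peak_id
    missing_peaks <- setdiff(expected, colnames(values))
    if (length(missing_peaks) > 0L) {
      stop("peak matrix ", path, " lacks column(s): ",
        paste(missing_peaks, collapse = ", "), call. = FALSE)
    }
  }
  attr(values, "kind") <- kind
  values
}

#' Write a sample-by-feature matrix to TSV
#'
#' Inverse of [read_matrix()]: header `sample_id` + feature ids, missing
#' values as empty cells, numbers at 6 significant digits unless
#' `full_precision` is set.
#'
#' @param mat Numeric matrix with sample row names.
#' @param path Output path.
#' @param full_precision Write full double precision instead of 6
#'   significant digits.
#' @return Invisibly `path`.
#' @export
write_matrix <- function(mat, path, full_precision = FALSE) {
  stopifnot(is.matrix(mat))
  fmt <- function(x) {
    out <- if (full_precision) {
      vapply(x, function(v) format(v, digits = 17, scientific = FALSE), "")
    } else {
      vapply(x, function(v) as.character(signif(v, 6)), "")
    }
    out[is.na(x)] <- ""
    out
  }
  lines <- c(
    paste(c("sample_id", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the full discovery-replication pipeline
#'
#' Executes the end-to-end protocol on either synthetic or file-based
#' cohorts: derive the 113 glycan traits from peak percentages,
#' inverse-normal scale proteins and traits per cohort, align features
#' across cohorts, scan all pairs in the discovery cohort at the Bonferroni
#' level, replicate nominally with sign consistency, and assemble the
#' signed-r-squared association matrix.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   * `synthetic`: a [synthetic_config()] (or its argument list), or
#'   * `discovery_proteins`, `discovery_peaks`, `replication_proteins`,
#'     `replication_peaks`: paths to TSV matrices (peaks may be raw areas;
#'     set `peaks_are_areas = TRUE` to renormalize);
#'   * optional `alpha` (default 0.05), `replication_p` (default 0.05),
#'     `inverse_normal_offset` (default 3/8), `swap_roles` (default `FALSE`;
#'     if `TRUE` the two cohorts exchange discovery/replication roles),
#'     `out_dir` (when set, `records.tsv`, `matrix.tsv` and `summary.json`
#'     are written there).
#' @return A list with `records`, `matrix`, `summary`, `truth` (synthetic
#'   runs only) and `report` (feature alignment report).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  alpha <- config$alpha %||% 0.05
  rep_p <- config$replication_p %||% 0.05
  offset <- config$inverse_normal_offset %||% (3 / 8)
  annotations <- builtin_peak_annotations()
  catalog <- builtin_catalog(annotations)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    if (!inherits(sc, "synthetic_config")) {
      sc <- do.call(synthetic_config, sc)
    }
    cohorts <- generate_cohorts(sc, catalog, annotations)
    disc_prot <- cohorts$discovery$proteins
    disc_peak <- cohorts$discovery$peaks
    rep_prot <- cohorts$replication$proteins
    rep_peak <- cohorts$replication$peaks
    truth <- cohorts$truth
  } else {
    needed <- c("discovery_proteins", "discovery_peaks",
      "replication_proteins", "replication_peaks")
    missing_keys <- needed[vapply(config[needed], is.null, TRUE)]
    if (length(missing_keys) > 0L) {
      stop("pipeline config lacks input(s): ", paste(missing_keys, collapse = ", "),
        call. = FALSE)
    }
    for (key in needed) {
      if (!file.exists(config[[key]])) {
        stop("validation error: input path does not exist: ", config[[key]],
          call. = FALSE)
      }
    }
    disc_prot <- read_matrix(config$discovery_proteins, "protein")
    disc_peak <- read_matrix(config$discovery_peaks, "peak")
    rep_prot <- read_matrix(config$replication_proteins, "protein")
    rep_peak <- read_matrix(config$replication_peaks, "peak")
    if (isTRUE(config$peaks_are_areas)) {
      disc_peak <- normalize_peak_matrix(disc_peak, annotations)
      rep_peak <- normalize_peak_matrix(rep_peak, annotations)
    }
  }

  if (isTRUE(config$swap_roles)) {
    tmp <- list(disc_prot, disc_peak)
    disc_prot <- rep_prot
    disc_peak <- rep_peak
    rep_prot <- tmp[[1L]]
    rep_peak <- tmp[[2L]]
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
  }

  disc_traits <- stage("derive-traits", derive_all(disc_peak, catalog, annotations))
  rep_traits <- stage("derive-traits", derive_all(rep_peak, catalog, annotations))

  disc_prot_s <- stage("scale", inverse_normal_matrix(disc_prot, offset))
  rep_prot_s <- stage("scale", inverse_normal_matrix(rep_prot, offset))
  disc_traits_s <- stage("scale", inverse_normal_matrix(disc_traits, offset))
  rep_traits_s <- stage("scale", inverse_normal_matrix(rep_traits, offset))

  prot_al <- stage("align", align_cohorts(disc_prot_s, rep_prot_s))
  trait_al <- stage("align", align_cohorts(disc_traits_s, rep_traits_s))

  records <- stage("associate",
    discovery_scan(prot_al$discovery, trait_al$discovery, alpha))
  records <- stage("replicate",
    replicate_associations(records, prot_al$replication, trait_al$replication,
      p_cutoff = rep_p))
  assoc_mat <- stage("matrix", suppressWarnings(association_matrix(records)))

  counts <- status_counts(records)
  summary <- list(
    n_samples_discovery = nrow(disc_prot),
    n_samples_replication = nrow(rep_prot),
    n_proteins = prot_al$report$n_common,
    n_glycan_traits = trait_al$report$n_common,
    alpha = alpha,
    bonferroni_threshold = attr(records, "threshold"),
    replication_p_cutoff = rep_p,
    counts = as.list(counts),
    n_matrix_glycans = nrow(assoc_mat),
    n_matrix_proteins = ncol(assoc_mat)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(records),
      file.path(config$out_dir, "records.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(assoc_mat) > 0L) {
      write_matrix(assoc_mat, file.path(config$out_dir, "matrix.tsv"))
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(records = records, matrix = assoc_mat, summary = summary,
    truth = truth,
    report = list(proteins = prot_al$report, glycans = trait_al$report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
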