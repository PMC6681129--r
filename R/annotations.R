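# Chromatographic peak annotations --------------------------------------------
#
# HILIC-UPLC resolves the 2-AB-labelled total plasma N-glycome into 36 glycan
# peaks (GP1-GP36). Each peak may contain several co-eluting structures; group
# membership of a peak in a derived trait is decided by its *dominant*
# (first-listed, unless stated otherwise) structure. The assignment is shipped
# as a plain-text table so users can swap in an alternative assignment.
# The shipped table is a curated, synthetic-but-structure-coherent transcription
# of the standard plasma peak assignment used with this peak layout.

#' Read a peak annotation table
#'
#' The table is a TSV with columns `peak_id`, `structure_labels`
#' (`" + "`-separated Oxford-notation labels of the co-eluting structures) and
#' `dominant_index` (1-based index of the dominant structure, normally 1).
#' All labels are parsed on load, so a malformed label fails here, loudly.
#'
#' @param path Path to the TSV file.
#' @return An object of class `peak_annotation`: a data frame with one row
#'   per peak and list-columns `structures` (parsed `glycan_structure`s) and
#'   `dominant` (the dominant parsed structure).
#' @export
read_peak_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("peak_id", "structure_labels", "dominant_index")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop(
      "peak annotation table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(tab$peak_id)) {
    dup <- unique(tab$peak_id[duplicated(tab$peak_id)])
    stop("duplicate peak_id(s) in annotation table: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  labels <- strsplit(tab$structure_labels, " + ", fixed = TRUE)
  if (any(lengths(labels) == 0L)) {
    stop("empty structure list for peak ", tab$peak_id[lengths(labels) == 0L][1], call. = FALSE)
  }
  structures <- lapply(labels, function(ls) lapply(trimws(ls), parse_structure))
  dom_idx <- as.integer(tab$dominant_index)
  bad <- which(is.na(dom_idx) | dom_idx < 1L | dom_idx > lengths(structures))
  if (length(bad) > 0L) {
    stop(
      "dominant_index out of range for peak ", tab$peak_id[bad[1]],
      call. = FALSE
    )
  }
  out <- data.frame(
    peak_id = tab$peak_id,
    structure_labels = tab$structure_labels,
    dominant_index = dom_idx,
    stringsAsFactors = FALSE
  )
  out$structures <- structures
  out$dominant <- mapply(function(s, i) s[[i]], structures, dom_idx, SIMPLIFY = FALSE)
  class(out) <- c("peak_annotation", "data.frame")
  out
}

.annotation_cache <- new.env(parent = emptyenv())

#' The shipped 36-peak plasma N-glycome annotation
#'
#' Returns the peak assignment distributed with the package
#' (`inst/extdata/peak_annotations.tsv`): 36 peaks GP1-GP36 covering the
#' neutral biantennary region through the tetrasialylated tetraantennary
#' region, with co-eluting structures listed per peak.
#'
#' @return A `peak_annotation` (see [read_peak_annotations()]).
#' @export
builtin_peak_annotations <- function() {
  if (is.null(.annotation_cache$builtin)) {
    path <- system.file("extdata", "peak_annotations.tsv",
      package = "glycoproteomap", mustWork = TRUE
    )
    .annotation_cache$builtin <- read_peak_annotations(path)
  }
  .annotation_cache$builtin
}

#' Peaks whose dominant structure is neutral (unsialylated)
#'
#' The "total neutral plasma glycans" (GPn) denominator: every peak whose
#' dominant structure carries no sialic acid, including the high-mannose
#' peaks.
#'
#' @param annotations A `peak_annotation`.
#' @return Character vector of peak ids.
#' @export
neutral_peaks <- function(annotations = builtin_peak_annotations()) {
  stopifnot(inherits(annotations, "peak_annotation"))
  sial <- vapply(annotations$dominant, function(s) s$sialic_acids, integer(1))
  annotations$peak_id[sial == 0L]
}

#' Select peaks whose dominant structure matches a predicate
#'
#' @param annotations A `peak_annotation`.
#' @param predicate A [glycan_predicate()].
#' @return Character vector of matching peak ids.
#' @export
match_peaks <- function(annotations, predicate) {
  stopifnot(inherits(annotations, "peak_annotation"))
  hit <- vapply(annotations$dominant, matches, logical(1), predicate = predicate)
  annotations$peak_id[hit]
}
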