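# Oxford-notation N-glycan structure labels -----------------------------------
#
# Grammar (one structure, no " + " composites):
#   high-mannose:  M<d>                      e.g. "M9"
#   complex:       [F] A<d> [F<d>] [(3|6)] [B] [G<d>] [S[(l,...)]<d>]
#                  e.g. "FA2BG2S(3,6)2", "A2(6)BG1", "A4F1G3S(3,3,6)3"
# A leading "F" is a core fucose (alpha1-6 on the inner GlcNAc); "F<d>" after
# the antenna count is antennary fucose. "B" is a bisecting GlcNAc. The
# parenthesised arm before "B"/"G" marks which trimannosyl arm carries a
# single galactose. "S(3,6)2" gives the sialic linkages positionally; a bare
# "S<d>" leaves them unspecified (isomers not separated chromatographically).

#' Parse an Oxford-notation glycan structure label
#'
#' Turns a single structure label such as `"FA2BG2S(3,6)2"` or `"M9"` into a
#' `glycan_structure` record of structural features: family (complex vs
#' high-mannose), antenna count, core and antennary fucosylation, bisecting
#' GlcNAc, galactose count (and arm, when annotated), and sialic acid count
#' with per-residue linkages.
#'
#' Composite chromatographic peak labels joined by `" + "` are rejected here;
#' they belong to the peak annotation table (see
#' [read_peak_annotations()]), which splits them before parsing.
#'
#' @param label A single character string in Oxford notation.
#' @return An object of class `glycan_structure`: a list with fields
#'   `raw_label`, `family` (`"complex"` or `"high_mannose"`), `antennae`,
#'   `core_fucose`, `bisecting_glcnac`, `antennary_fucoses`, `galactoses`,
#'   `galactose_arm` (`"arm3"`, `"arm6"` or `"unspecified"`), `sialic_acids`,
#'   `sialic_linkages` (integer vector, one entry per sialic acid, `NA` when
#'   the linkage is not annotated) and `mannoses` (the core value 3 for
#'   complex structures).
#' @examples
#' parse_structure("FA2BG2S(3,6)2")
#' parse_structure("A2(6)BG1")
#' parse_structure("M9")
#' @seealso [format_structure()] for the inverse, [glycan_predicate()] for
#'   structural queries.
#' @export
parse_structure <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("`label` must be a single character string", call. = FALSE)
  }
  raw <- label
  label <- trimws(label)
  if (!nzchar(label)) {
    stop("empty glycan structure label", call. = FALSE)
  }
  if (grepl("+", label, fixed = TRUE)) {
    stop(
      "composite peak label '", raw, "' contains '+'; parse its members ",
      "individually (see read_peak_annotations())",
      call. = FALSE
    )
  }

  # High-mannose: M<d>, nothing else.
  if (grepl("^F?M", label)) {
    if (startsWith(label, "F")) {
      stop(
        "parse error in '", raw, "': core fucose ('F') is not defined for ",
        "high-mannose structures",
        call. = FALSE
      )
    }
    m <- regmatches(label, regexec("^M([0-9]+)$", label))[[1]]
    if (length(m) == 0L) {
      stop("parse error in '", raw, "': malformed high-mannose token", call. = FALSE)
    }
    mannoses <- as.integer(m[2])
    if (mannoses < 5L) {
      stop(
        "structural-consistency error in '", raw, "': high-mannose ",
        "structures carry at least 5 mannoses",
        call. = FALSE
      )
    }
    return(new_glycan_structure(
      raw_label = raw, family = "high_mannose", antennae = 0L,
      core_fucose = FALSE, bisecting_glcnac = FALSE, antennary_fucoses = 0L,
      galactoses = 0L, galactose_arm = "unspecified", sialic_acids = 0L,
      sialic_linkages = integer(0), mannoses = mannoses
    ))
  }

  pattern <- paste0(
    "^(F)?",                    # core fucose
    "A([0-9])",                 # antennae
    "(F([0-9]))?",              # antennary fucoses
    "(\\(([36])\\))?",          # arm annotation before B
    "(B)?",                     # bisecting GlcNAc
    "(\\(([36])\\))?",          # arm annotation after B
    "(G([0-9]))?",              # galactoses
    "(S(\\(([0-9,]+)\\))?([0-9]))?",  # sialic acids + optional linkages
    "$"
  )
  m <- regmatches(label, regexec(pattern, label))[[1]]
  if (length(m) == 0L) {
    bad <- sub("^F?A[0-9](F[0-9])?(\\([36]\\))?B?(\\([36]\\))?(G[0-9])?", "", label)
    if (!nzchar(bad)) bad <- label
    stop("parse error in '", raw, "': unrecognized token '", bad, "'", call. = FALSE)
  }

  antennae <- as.integer(m[3])
  core_fucose <- nzchar(m[2])
  antennary_fucoses <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  bisecting <- nzchar(m[8])
  arm_pre <- m[7]
  arm_post <- m[10]
  if (nzchar(arm_pre) && nzchar(arm_post)) {
    stop("parse error in '", raw, "': duplicate arm annotation", call. = FALSE)
  }
  arm_digit <- if (nzchar(arm_pre)) arm_pre else arm_post
  galactoses <- if (nzchar(m[12])) as.integer(m[12]) else 0L
  sialic_acids <- if (nzchar(m[13])) as.integer(m[16]) else 0L
  linkage_txt <- m[15]

  if (nzchar(arm_digit) && galactoses != 1L) {
    stop(
      "structural-consistency error in '", raw, "': an arm annotation ('(",
      arm_digit, ")') requires exactly one galactose",
      call. = FALSE
    )
  }
  galactose_arm <- if (!nzchar(arm_digit)) {
    "unspecified"
  } else if (arm_digit == "3") "arm3" else "arm6"

  if (nzchar(linkage_txt)) {
    linkages <- suppressWarnings(as.integer(strsplit(linkage_txt, ",", fixed = TRUE)[[1]]))
    if (anyNA(linkages) || !all(linkages %in% c(3L, 6L))) {
      stop(
        "parse error in '", raw, "': sialic linkages must be 3 or 6, got 'S(",
        linkage_txt, ")'",
        call. = FALSE
      )
    }
    if (length(linkages) != sialic_acids) {
      stop(
        "structural-consistency error in '", raw, "': ", length(linkages),
        " linkage(s) annotated for ", sialic_acids, " sialic acid(s)",
        call. = FALSE
      )
    }
  } else {
    linkages <- rep(NA_integer_, sialic_acids)
  }

  if (antennae < 1L || antennae > 4L) {
    stop(
      "structural-consistency error in '", raw, "': antenna count must be ",
      "between 1 and 4",
      call. = FALSE
    )
  }
  if (galactoses > antennae) {
    stop(
      "structural-consistency error in '", raw, "': galactoses (", galactoses,
      ") exceed antennae (", antennae, ")",
      call. = FALSE
    )
  }
  if (sialic_acids > galactoses) {
    stop(
      "structural-consistency error in '", raw, "': sialic acids (",
      sialic_acids, ") exceed galactoses (", galactoses, ")",
      call. = FALSE
    )
  }
  if (antennary_fucoses > antennae) {
    stop(
      "structural-consistency error in '", raw, "': antennary fucoses (",
      antennary_fucoses, ") exceed antennae (", antennae, ")",
      call. = FALSE
    )
  }

  new_glycan_structure(
    raw_label = raw, family = "complex", antennae = antennae,
    core_fucose = core_fucose, bisecting_glcnac = bisecting,
    antennary_fucoses = antennary_fucoses, galactoses = galactoses,
    galactose_arm = galactose_arm, sialic_acids = sialic_acids,
    sialic_linkages = linkages, mannoses = 3L
  )
}

new_glycan_structure <- function(raw_label, family, antennae, core_fucose,
                                 bisecting_glcnac, antennary_fucoses,
                                 galactoses, galactose_arm, sialic_acids,
                                 sialic_linkages, mannoses) {
  structure(
    list(
      raw_label = raw_label, family = family, antennae = antennae,
      core_fucose = core_fucose, bisecting_glcnac = bisecting_glcnac,
      antennary_fucoses = antennary_fucoses, galactoses = galactoses,
      galactose_arm = galactose_arm, sialic_acids = sialic_acids,
      sialic_linkages = sialic_linkages, mannoses = mannoses
    ),
    class = "glycan_structure"
  )
}

#' Format a glycan structure back to its Oxford-notation label
#'
#' Inverse of [parse_structure()]: `format_structure(parse_structure(x))`
#' reproduces `x` for every canonical label, including arm annotations
#' (printed directly after the antenna block, as in `"A2(6)BG1"`) and sialic
#' linkage lists (printed positionally, as in `"S(3,3,6)3"`; fully
#' unannotated linkages print as a bare count, `"S1"`).
#'
#' @param x A `glycan_structure`.
#' @return A single character string.
#' @export
format_structure <- function(x) {
  stopifnot(inherits(x, "glycan_structure"))
  if (x$family == "high_mannose") {
    return(paste0("M", x$mannoses))
  }
  out <- character(0)
  if (x$core_fucose) out <- c(out, "F")
  out <- c(out, paste0("A", x$antennae))
  if (x$antennary_fucoses > 0L) out <- c(out, paste0("F", x$antennary_fucoses))
  if (x$galactose_arm != "unspecified") {
    out <- c(out, paste0("(", if (x$galactose_arm == "arm3") "3" else "6", ")"))
  }
  if (x$bisecting_glcnac) out <- c(out, "B")
  if (x$galactoses > 0L) out <- c(out, paste0("G", x$galactoses))
  if (x$sialic_acids > 0L) {
    if (all(is.na(x$sialic_linkages))) {
      out <- c(out, paste0("S", x$sialic_acids))
    } else {
      out <- c(out, paste0(
        "S(", paste(x$sialic_linkages, collapse = ","), ")", x$sialic_acids
      ))
    }
  }
  paste(out, collapse = "")
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan_structure> ", format_structure(x), "\n", sep = "")
  if (x$family == "high_mannose") {
    cat("  high-mannose, ", x$mannoses, " mannoses\n", sep = "")
  } else {
    feats <- c(
      sprintf("%d antennae", x$antennae),
      if (x$core_fucose) "core fucose",
      if (x$antennary_fucoses > 0L) sprintf("%d antennary fucose(s)", x$antennary_fucoses),
      if (x$bisecting_glcnac) "bisecting GlcNAc",
      sprintf("%d galactose(s)", x$galactoses),
      if (x$galactose_arm != "unspecified") paste0("on ", sub("arm", "alpha1-", x$galactose_arm), " arm"),
      sprintf("%d sialic acid(s)", x$sialic_acids)
    )
    cat("  complex:", paste(feats, collapse = ", "), "\n")
  }
  invisible(x)
}

# Structural predicates --------------------------------------------------------

.predicate_fields <- c(
  "family", "antennae", "core_fucose", "bisecting_glcnac",
  "antennary_fucoses", "galactoses", "galactose_arm", "sialic_acids",
  "mannoses"
)

.predicate_ops <- c("eq", "ne", "ge", "le", "gt", "lt")

#' Comparators for predicate clauses
#'
#' Wrap a clause value to compare with something other than equality, e.g.
#' `glycan_predicate(antennary_fucoses = at_least(1))`.
#'
#' @param value Comparison value.
#' @return A tagged value understood by [glycan_predicate()].
#' @name predicate-comparators
NULL

#' @rdname predicate-comparators
#' @export
at_least <- function(value) structure(list(op = "ge", value = value), class = "predicate_clause_value")

#' @rdname predicate-comparators
#' @export
at_most <- function(value) structure(list(op = "le", value = value), class = "predicate_clause_value")

#' @rdname predicate-comparators
#' @export
not_equal <- function(value) structure(list(op = "ne", value = value), class = "predicate_clause_value")

#' Build a structural predicate over glycan features
#'
#' A predicate is a conjunction of field comparisons evaluated against a
#' `glycan_structure` by [matches()]. Named arguments give the clauses; plain
#' values mean equality, and [at_least()], [at_most()], [not_equal()] wrap
#' other comparators. An empty predicate matches everything.
#'
#' Predicates are the selection language of the trait catalog: e.g. the
#' "trisialylated structures" group is `glycan_predicate(sialic_acids = 3)`
#' and "core fucosylated structures" is
#' `glycan_predicate(core_fucose = TRUE)`.
#'
#' @param ... Named clauses over the fields `family`, `antennae`,
#'   `core_fucose`, `bisecting_glcnac`, `antennary_fucoses`, `galactoses`,
#'   `galactose_arm`, `sialic_acids`, `mannoses`.
#' @return An object of class `glycan_predicate`.
#' @examples
#' trisialylated <- glycan_predicate(sialic_acids = 3)
#' matches(parse_structure("A3G3S(3,3,3)3"), trisialylated)
#' @export
glycan_predicate <- function(...) {
  clauses <- list(...)
  if (length(clauses) > 0L) {
    nm <- names(clauses)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("all predicate clauses must be named", call. = FALSE)
    }
    bad <- setdiff(nm, .predicate_fields)
    if (length(bad) > 0L) {
      stop(
        "unknown glycan structure field(s) in predicate: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  out <- lapply(seq_along(clauses), function(i) {
    v <- clauses[[i]]
    if (inherits(v, "predicate_clause_value")) {
      list(field = names(clauses)[i], op = v$op, value = v$value)
    } else {
      list(field = names(clauses)[i], op = "eq", value = v)
    }
  })
  structure(out, class = "glycan_predicate")
}

#' Evaluate a structural predicate on a parsed glycan structure
#'
#' @param structure A `glycan_structure` from [parse_structure()].
#' @param predicate A `glycan_predicate`.
#' @return `TRUE` iff every clause holds (an empty predicate returns `TRUE`).
#' @export
matches <- function(structure, predicate) {
  stopifnot(inherits(structure, "glycan_structure"))
  if (!inherits(predicate, "glycan_predicate")) {
    stop("`predicate` must be a glycan_predicate", call. = FALSE)
  }
  for (cl in predicate) {
    if (!cl$field %in% .predicate_fields) {
      stop("unknown glycan structure field in predicate: ", cl$field, call. = FALSE)
    }
    actual <- structure[[cl$field]]
    ok <- switch(cl$op,
      eq = identical(as.vector(actual), as.vector(cl$value)) ||
        (is.numeric(actual) && is.numeric(cl$value) && actual == cl$value),
      ne = !(identical(as.vector(actual), as.vector(cl$value)) ||
        (is.numeric(actual) && is.numeric(cl$value) && actual == cl$value)),
      ge = actual >= cl$value,
      le = actual <= cl$value,
      gt = actual > cl$value,
      lt = actual < cl$value,
      stop("unknown predicate comparator: ", cl$op, call. = FALSE)
    )
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' @export
print.glycan_predicate <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<glycan_predicate> (matches everything)\n")
    return(invisible(x))
  }
  sym <- c(eq = "=", ne = "!=", ge = ">=", le = "<=", gt = ">", lt = "<")
  txt <- vapply(x, function(cl) paste(cl$field, sym[[cl$op]], cl$value), "")
  cat("<glycan_predicate>", paste(txt, collapse = " & "), "\n")
  invisible(x)
}

# JSON-friendly (de)serialization used by the catalog file format.
predicate_to_list <- function(predicate) {
  lapply(predicate, function(cl) {
    list(field = cl$field, op = cl$op, value = cl$value)
  })
}

predicate_from_list <- function(x) {
  out <- lapply(x, function(cl) {
    if (is.null(cl$field) || is.null(cl$op)) {
      stop("malformed predicate clause in catalog", call. = FALSE)
    }
    if (!cl$field %in% .predicate_fields) {
      stop("unknown glycan structure field in predicate: ", cl$field, call. = FALSE)
    }
    if (!cl$op %in% .predicate_ops) {
      stop("unknown predicate comparator: ", cl$op, call. = FALSE)
    }
    value <- cl$value
    if (cl$field %in% c("family", "galactose_arm")) {
      value <- as.character(value)
    } else if (cl$field %in% c("core_fucose", "bisecting_glcnac")) {
      value <- as.logical(value)
    } else {
      value <- as.numeric(value)
    }
    list(field = cl$field, op = cl$op, value = value)
  })
  structure(out, class = "glycan_predicate")
}
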