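# Glycan trait catalog ---------------------------------------------------------
#
# A trait catalog is a declarative recipe set mapping the 36 peak percentages
# to 113 glycan traits:
#   * 36 primary traits   - one peak's percent of total integrated area;
#   * 77 derived traits   - group percentages (all peaks whose dominant
#     structure matches a predicate), sub-fraction percentages (matching peaks
#     as a percentage of a predicate- or neutral-selected denominator set),
#     percentages within the neutral subprofile (GPn), and ratios of two
#     previously defined traits.
# Derived-trait ids follow the conventional plasma derived-trait scheme; the
# traits that are individually named in published plasma glycome-proteome work
# (e.g. PGP93 core fucosylated structures, PGP97 trisialylated structures,
# PGP69 M9 in total neutral plasma glycans) sit at their conventional ids.

new_trait <- function(trait_id, name, kind,
                      peaks = NULL,
                      numerator_predicate = NULL,
                      denominator = "total",
                      denominator_predicate = NULL,
                      num_trait = NULL, den_trait = NULL,
                      provenance = "scheme") {
  structure(
    list(
      trait_id = trait_id, name = name, kind = kind, peaks = peaks,
      numerator_predicate = numerator_predicate,
      denominator = denominator,
      denominator_predicate = denominator_predicate,
      num_trait = num_trait, den_trait = den_trait,
      provenance = provenance
    ),
    class = "trait_definition"
  )
}

#' @export
print.trait_definition <- function(x, ...) {
  cat(sprintf("<trait_definition> %s [%s]: %s\n", x$trait_id, x$kind, x$name))
  invisible(x)
}

new_trait_catalog <- function(traits, version = "1.0") {
  ids <- vapply(traits, function(t) t$trait_id, "")
  names(traits) <- ids
  structure(list(traits = traits, version = version), class = "trait_catalog")
}

#' @export
print.trait_catalog <- function(x, ...) {
  kinds <- vapply(x$traits, function(t) t$kind, "")
  cat(sprintf(
    "<trait_catalog> %d traits (%d primary, %d derived; version %s)\n",
    length(x$traits), sum(kinds == "primary"), sum(kinds != "primary"),
    x$version
  ))
  invisible(x)
}

#' @export
length.trait_catalog <- function(x) length(x$traits)

#' Summarize a trait catalog as a data frame
#'
#' @param x A `trait_catalog`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return A data frame with columns `trait_id`, `name`, `kind`,
#'   `provenance`.
#' @export
as.data.frame.trait_catalog <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    trait_id = vapply(x$traits, function(t) t$trait_id, ""),
    name = vapply(x$traits, function(t) t$name, ""),
    kind = vapply(x$traits, function(t) t$kind, ""),
    provenance = vapply(x$traits, function(t) t$provenance, ""),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' The shipped 113-trait plasma N-glycome catalog
#'
#' Returns the catalog of 36 primary traits (PGP1-PGP36, the percent of each
#' chromatographic peak GP1-GP36 in the total integrated area) and 77 derived
#' traits (PGP37-PGP113): core-fucosylation/bisecting sialylation
#' sub-fractions and ratios, the neutral subprofile (GPn) percentages,
#' global sialylation/galactosylation/branching group percentages, and
#' branching/sialylation ratios.
#'
#' @param annotations A `peak_annotation`; used for the primary trait names
#'   and to resolve the neutral peak set.
#' @return A `trait_catalog` with 113 traits, validated against
#'   `annotations` (see [validate_catalog()]).
#' @examples
#' cat113 <- builtin_catalog()
#' table(as.data.frame(cat113)$kind)
#' @export
builtin_catalog <- function(annotations = builtin_peak_annotations()) {
  default_ann <- identical(annotations, builtin_peak_annotations())
  if (default_ann && !is.null(.annotation_cache$catalog)) {
    return(.annotation_cache$catalog)
  }
  p <- glycan_predicate
  traits <- vector("list", 113L)

  # Primary traits: one peak each, percent of total integrated area.
  for (i in seq_len(36L)) {
    peak <- paste0("GP", i)
    row <- match(peak, annotations$peak_id)
    named_primary <- c(3L, 11L, 14L, 16L, 19L, 21L, 22L, 24L, 29L, 30L, 32L, 36L)
    traits[[i]] <- new_trait(
      trait_id = paste0("PGP", i),
      name = annotations$structure_labels[row],
      kind = "primary", peaks = peak,
      provenance = if (i %in% named_primary) "reported" else "scheme"
    )
  }

  grp <- function(id, name, pred, provenance = "scheme") {
    new_trait(paste0("PGP", id), name, "group_percent",
      numerator_predicate = pred, provenance = provenance
    )
  }
  sub <- function(id, name, num, den, provenance = "scheme") {
    new_trait(paste0("PGP", id), name, "subfraction_percent",
      numerator_predicate = num, denominator = "predicate",
      denominator_predicate = den, provenance = provenance
    )
  }
  subn <- function(id, name, num, provenance = "scheme") {
    new_trait(paste0("PGP", id), name, "subfraction_percent",
      numerator_predicate = num, denominator = "neutral_total",
      provenance = provenance
    )
  }
  rat <- function(id, name, num_id, den_id, provenance = "scheme") {
    new_trait(paste0("PGP", id), name, "ratio",
      num_trait = paste0("PGP", num_id), den_trait = paste0("PGP", den_id),
      provenance = provenance
    )
  }

  # Core-fucosylation / bisecting sialylation block (FS0/FS1/FS2 families).
  traits[[37]] <- grp(37, "core fucosylated neutral structures",
    p(core_fucose = TRUE, sialic_acids = 0))
  traits[[38]] <- grp(38, "core fucosylated monosialylated structures",
    p(core_fucose = TRUE, sialic_acids = 1))
  traits[[39]] <- grp(39, "core fucosylated disialylated structures",
    p(core_fucose = TRUE, sialic_acids = 2))
  traits[[40]] <- grp(40, "core fucosylated neutral structures with bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = TRUE, sialic_acids = 0))
  traits[[41]] <- grp(41, "core fucosylated neutral structures without bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = FALSE, sialic_acids = 0))
  traits[[42]] <- sub(42,
    "monosialylation of core-fucosylated digalactosylated structures without bisecting GlcNAc",
    p(sialic_acids = 1),
    p(core_fucose = TRUE, bisecting_glcnac = FALSE, galactoses = 2),
    provenance = "reported")
  traits[[43]] <- grp(43, "core fucosylated monosialylated structures without bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = FALSE, sialic_acids = 1))
  traits[[44]] <- sub(44,
    "monosialylation of core-fucosylated digalactosylated structures with bisecting GlcNAc",
    p(sialic_acids = 1),
    p(core_fucose = TRUE, bisecting_glcnac = TRUE, galactoses = 2),
    provenance = "reported")
  traits[[45]] <- grp(45, "core fucosylated monosialylated structures with bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = TRUE, sialic_acids = 1))
  traits[[46]] <- grp(46, "core fucosylated disialylated structures without bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = FALSE, sialic_acids = 2))
  traits[[47]] <- grp(47, "core fucosylated disialylated structures with bisecting GlcNAc",
    p(core_fucose = TRUE, bisecting_glcnac = TRUE, sialic_acids = 2))
  traits[[48]] <- rat(48,
    "ratio of fucosylated monosialylated and disialylated structures with bisecting GlcNAc",
    45, 47, provenance = "reported")
  traits[[49]] <- rat(49,
    "ratio of fucosylated monosialylated and disialylated structures without bisecting GlcNAc",
    43, 46)
  traits[[50]] <- rat(50, "ratio of fucosylated monosialylated and disialylated structures",
    38, 39)
  traits[[51]] <- rat(51, "ratio of fucosylated neutral structures with and without bisecting GlcNAc",
    40, 41)
  traits[[52]] <- sub(52, "incidence of bisecting GlcNAc in all fucosylated neutral structures",
    p(bisecting_glcnac = TRUE),
    p(core_fucose = TRUE, sialic_acids = 0))
  traits[[53]] <- rat(53, "ratio of fucosylated disialylated structures with and without bisecting GlcNAc",
    47, 46)
  traits[[54]] <- rat(54, "ratio of fucosylated monosialylated structures with and without bisecting GlcNAc",
    45, 43, provenance = "reported")
  traits[[55]] <- sub(55, "the incidence of bisecting GlcNAc in all fucosylated monosialylated structures",
    p(bisecting_glcnac = TRUE),
    p(core_fucose = TRUE, sialic_acids = 1),
    provenance = "reported")
  traits[[56]] <- sub(56, "incidence of bisecting GlcNAc in all fucosylated disialylated structures",
    p(bisecting_glcnac = TRUE),
    p(core_fucose = TRUE, sialic_acids = 2))
  traits[[57]] <- sub(57, "disialylation of core-fucosylated digalactosylated structures",
    p(sialic_acids = 2),
    p(core_fucose = TRUE, galactoses = 2))

  # Neutral subprofile: percent of each neutral peak within the neutral total.
  neutral <- neutral_peaks(annotations)
  named_gpn <- c("GP8" = "reported", "GP18" = "reported")
  for (j in seq_along(neutral)) {
    peak <- neutral[j]
    row <- match(peak, annotations$peak_id)
    id <- 57L + j
    traits[[id]] <- new_trait(
      trait_id = paste0("PGP", id),
      name = paste0(
        annotations$structure_labels[row],
        " in total neutral plasma glycans (GPn)"
      ),
      kind = "subfraction_percent", peaks = peak,
      denominator = "neutral_total",
      provenance = if (!is.na(named_gpn[peak])) "reported" else "scheme"
    )
  }

  traits[[70]] <- subn(70, "agalactosylated structures in total neutral plasma glycans",
    p(family = "complex", galactoses = 0))
  traits[[71]] <- subn(71, "monogalactosylated structures in total neutral plasma glycans",
    p(galactoses = 1))
  traits[[72]] <- subn(72, "digalactosylated structures in total neutral plasma glycans",
    p(galactoses = 2))
  traits[[73]] <- subn(73, "high-mannose structures in total neutral plasma glycans",
    p(family = "high_mannose"))
  traits[[74]] <- subn(74, "structures with bisecting GlcNAc in total neutral plasma glycans",
    p(bisecting_glcnac = TRUE))
  traits[[75]] <- sub(75, "fucosylation of digalactosylated structures in total neutral plasma glycans",
    p(core_fucose = TRUE),
    p(galactoses = 2, sialic_acids = 0),
    provenance = "reported")

  # Global sialylation composition.
  traits[[76]] <- grp(76, "neutral structures in total plasma glycans",
    p(sialic_acids = 0))
  traits[[77]] <- grp(77, "sialylated structures in total plasma glycans",
    p(sialic_acids = at_least(1)))
  traits[[78]] <- sub(78, "monosialylated structures in total sialylated structures",
    p(sialic_acids = 1), p(sialic_acids = at_least(1)))
  traits[[79]] <- sub(79, "disialylated structures in total sialylated structures",
    p(sialic_acids = 2), p(sialic_acids = at_least(1)))
  traits[[80]] <- sub(80, "trisialylated structures in total sialylated structures",
    p(sialic_acids = 3), p(sialic_acids = at_least(1)))
  traits[[81]] <- sub(81, "tetrasialylated structures in total sialylated structures",
    p(sialic_acids = 4), p(sialic_acids = at_least(1)))
  traits[[82]] <- sub(82, "core fucosylation of agalactosylated structures",
    p(core_fucose = TRUE), p(family = "complex", galactoses = 0))
  traits[[83]] <- sub(83, "incidence of bisecting GlcNAc in core fucosylated structures",
    p(bisecting_glcnac = TRUE), p(core_fucose = TRUE))
  traits[[84]] <- sub(84, "core fucosylation of sialylated structures",
    p(core_fucose = TRUE), p(sialic_acids = at_least(1)))
  traits[[85]] <- sub(85, "incidence of bisecting GlcNAc in sialylated structures",
    p(bisecting_glcnac = TRUE), p(sialic_acids = at_least(1)))
  traits[[86]] <- rat(86, "ratio of monosialylated and disialylated structures", 95, 96)
  traits[[87]] <- rat(87, "ratio of disialylated and trisialylated structures", 96, 97)
  traits[[88]] <- rat(88, "ratio of trisialylated and tetrasialylated structures", 97, 98)
  traits[[89]] <- rat(89, "ratio of biantennary and triantennary structures", 104, 105)
  traits[[90]] <- rat(90, "ratio of triantennary and tetraantennary structures", 105, 106)
  traits[[91]] <- rat(91, "ratio of core and antennary fucosylated structures", 93, 92)

  # Global group percentages.
  traits[[92]] <- grp(92, "antennary fucosylated structures",
    p(antennary_fucoses = at_least(1)), provenance = "reported")
  traits[[93]] <- grp(93, "core fucosylated structures",
    p(core_fucose = TRUE), provenance = "reported")
  traits[[94]] <- grp(94, "tri- and tetraantennary structures",
    p(antennae = at_least(3)))
  traits[[95]] <- grp(95, "monosialylated structures", p(sialic_acids = 1))
  traits[[96]] <- grp(96, "disialylated structures", p(sialic_acids = 2))
  traits[[97]] <- grp(97, "trisialylated structures", p(sialic_acids = 3),
    provenance = "reported")
  traits[[98]] <- grp(98, "tetrasialylated structures", p(sialic_acids = 4))
  traits[[99]] <- grp(99, "agalactosylated structures",
    p(family = "complex", galactoses = 0), provenance = "reported")
  traits[[100]] <- grp(100, "monogalactosylated structures", p(galactoses = 1))
  traits[[101]] <- grp(101, "digalactosylated structures", p(galactoses = 2))
  traits[[102]] <- grp(102, "trigalactosylated structures", p(galactoses = 3),
    provenance = "reported")
  traits[[103]] <- grp(103, "tetragalactosylated structures", p(galactoses = 4),
    provenance = "reported")
  traits[[104]] <- grp(104, "biantennary structures",
    p(family = "complex", antennae = 2))
  traits[[105]] <- grp(105, "triantennary structures", p(antennae = 3),
    provenance = "reported")
  traits[[106]] <- grp(106, "tetraantennary structures", p(antennae = 4),
    provenance = "reported")
  traits[[107]] <- grp(107, "high-mannose structures", p(family = "high_mannose"))
  traits[[108]] <- grp(108, "glycan structures with bisecting GlcNAc",
    p(bisecting_glcnac = TRUE), provenance = "reported")
  traits[[109]] <- grp(109, "trisialylated tetragalactosylated structures",
    p(galactoses = 4, sialic_acids = 3))
  traits[[110]] <- rat(110,
    "ratio of trisialylated and tetrasialylated tetragalactosylated structures",
    109, 111, provenance = "reported")
  traits[[111]] <- grp(111, "tetrasialylated tetragalactosylated structures",
    p(galactoses = 4, sialic_acids = 4))
  traits[[112]] <- sub(112, "antennary fucosylation of trigalactosylated structures",
    p(antennary_fucoses = at_least(1)), p(galactoses = 3),
    provenance = "reported")
  traits[[113]] <- sub(113, "antennary fucosylation of tetragalactosylated structures",
    p(antennary_fucoses = at_least(1)), p(galactoses = 4),
    provenance = "reported")

  catalog <- new_trait_catalog(traits)
  validate_catalog(catalog, annotations)
  if (default_ann) .annotation_cache$catalog <- catalog
  catalog
}

#' Validate a trait catalog against a peak annotation table
#'
#' Checks the structural invariants of a catalog: 113 traits in total, 36 of
#' kind `primary` and 77 derived; unique trait ids; every primary trait
#' referencing exactly one known peak with denominator `total`; every ratio
#' trait referencing existing traits without cycles; every referenced peak id
#' present in `annotations`.
#'
#' @param catalog A `trait_catalog`.
#' @param annotations A `peak_annotation`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_catalog <- function(catalog, annotations = builtin_peak_annotations()) {
  stopifnot(inherits(catalog, "trait_catalog"))
  traits <- catalog$traits
  ids <- vapply(traits, function(t) t$trait_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate trait ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE)
  }
  kinds <- vapply(traits, function(t) t$kind, "")
  bad_kind <- setdiff(kinds, c("primary", "group_percent", "subfraction_percent", "ratio"))
  if (length(bad_kind) > 0L) {
    stop("unknown trait kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (length(traits) != 113L || sum(kinds == "primary") != 36L) {
    stop(
      sprintf(
        "catalog must hold 113 traits with 36 primary; got %d with %d primary",
        length(traits), sum(kinds == "primary")
      ),
      call. = FALSE
    )
  }
  for (t in traits) {
    if (t$kind == "primary") {
      if (length(t$peaks) != 1L || t$denominator != "total") {
        stop("primary trait ", t$trait_id,
          " must reference exactly one peak with denominator 'total'",
          call. = FALSE)
      }
    }
    if (!is.null(t$peaks)) {
      unknown <- setdiff(t$peaks, annotations$peak_id)
      if (length(unknown) > 0L) {
        stop("trait ", t$trait_id, " references unknown peak(s): ",
          paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
    if (t$kind == "ratio") {
      for (ref in c(t$num_trait, t$den_trait)) {
        if (!ref %in% ids) {
          stop("ratio trait ", t$trait_id, " references unknown trait ", ref,
            call. = FALSE)
        }
        if (traits[[ref]]$kind == "ratio") {
          # One level of composition is enough for the shipped catalog and
          # keeps the dependency graph trivially acyclic.
          stop("ratio trait ", t$trait_id,
            " may not reference another ratio trait (", ref, ")",
            call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Count catalog traits by kind
#'
#' @param catalog A `trait_catalog`.
#' @return Named integer vector with elements `total`, `primary`, `derived`,
#'   plus one count per kind.
#' @export
catalog_counts <- function(catalog) {
  kinds <- vapply(catalog$traits, function(t) t$kind, "")
  c(
    total = length(kinds),
    primary = sum(kinds == "primary"),
    derived = sum(kinds != "primary"),
    table(kinds)
  )
}

# Catalog file format (JSON, versioned) ----------------------------------------

#' Write a trait catalog to its JSON file format
#'
#' @param catalog A `trait_catalog`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "trait_catalog"))
  ser <- list(
    format = "glycan-trait-catalog",
    version = catalog$version,
    traits = lapply(unname(catalog$traits), function(t) {
      out <- list(trait_id = t$trait_id, name = t$name, kind = t$kind)
      if (!is.null(t$peaks)) out$peaks <- as.list(t$peaks)
      if (!is.null(t$numerator_predicate)) {
        out$numerator_predicate <- predicate_to_list(t$numerator_predicate)
      }
      out$denominator <- t$denominator
      if (!is.null(t$denominator_predicate)) {
        out$denominator_predicate <- predicate_to_list(t$denominator_predicate)
      }
      if (!is.null(t$num_trait)) out$num_trait <- t$num_trait
      if (!is.null(t$den_trait)) out$den_trait <- t$den_trait
      out$provenance <- t$provenance
      out
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trait catalog from its JSON file format
#'
#' @param path Path to a catalog JSON written by [write_catalog()].
#' @return A `trait_catalog`.
#' @export
read_catalog <- function(path) {
  ser <- jsonlite::read_json(path)
  if (is.null(ser$format) || ser$format != "glycan-trait-catalog") {
    stop("not a glycan trait catalog file: ", path, call. = FALSE)
  }
  traits <- lapply(ser$traits, function(t) {
    new_trait(
      trait_id = t$trait_id, name = t$name, kind = t$kind,
      peaks = if (!is.null(t$peaks)) unlist(t$peaks),
      numerator_predicate = if (!is.null(t$numerator_predicate)) {
        predicate_from_list(t$numerator_predicate)
      },
      denominator = if (!is.null(t$denominator)) t$denominator else "total",
      denominator_predicate = if (!is.null(t$denominator_predicate)) {
        predicate_from_list(t$denominator_predicate)
      },
      num_trait = t$num_trait, den_trait = t$den_trait,
      provenance = if (!is.null(t$provenance)) t$provenance else "unknown"
    )
  })
  new_trait_catalog(traits, version = if (!is.null(ser$version)) ser$version else "1.0")
}
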