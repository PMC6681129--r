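# Synthetic paired glycome-proteome cohorts ------------------------------------
#
# Generative model: each plasma protein i carries a fixed glycoform
# composition profile phi_i over the 36 chromatographic peaks (a point on the
# simplex). A sample's raw glycome is the abundance-weighted mixture
#     g(s) = sum_i a_i(s) * phi_i  +  sum_b a_b(s) * phi_b
# over assayed proteins i and unassayed background proteins b, with
# log-normal abundances a. "Enzyme"-type links additionally scale designated
# peak fractions by a_i(s)^gamma (an abundance-dependent biosynthetic push)
# before renormalization. Each peak then receives independent multiplicative
# log-normal noise and the emitted peak table is the row-normalized percent
# composition; the emitted protein readout is log-abundance plus Gaussian
# noise (a monotone, noisy stand-in for an aptamer's relative fluorescence).
# Discovery and replication cohorts are drawn from identical parameters with
# independent sub-seeds.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the discovery/replication design the package targets: a
#' discovery cohort of 344 samples and a replication cohort of 46, protein
#' readouts as noisy log-abundances, and a glycome formed as an
#' abundance-weighted mixture of per-protein glycoform profiles with
#' multiplicative peak noise.
#'
#' @param n_discovery,n_replication Cohort sizes (>= 3).
#' @param n_proteins Number of assayed proteins (readout emitted).
#' @param n_background_proteins Unassayed proteins contributing glycome mass
#'   only.
#' @param glycoform_profiles Optional matrix of per-protein peak compositions
#'   (rows: assayed then background proteins; columns: peak ids; rows sum
#'   to 1). When `NULL`, profiles are drawn from a Dirichlet concentrated on
#'   a structure-coherent peak block per protein, so derived traits inherit
#'   realistic block correlation.
#' @param abundance_log_mean,abundance_log_sd Per-protein log-normal
#'   abundance parameters; scalars are recycled. Defaults: means drawn from
#'   N(0, 0.3), sd 0.35.
#' @param glycan_noise_cv Coefficient of variation of the multiplicative
#'   per-peak noise (0.1 = 10% measurement noise).
#' @param protein_readout_noise_sd Gaussian noise sd on the log-abundance
#'   readout.
#' @param planted_links List of links built with [planted_link()].
#' @param shared_profile If `TRUE`, all proteins share one common glycoform
#'   profile, so the peak composition carries no protein-specific signal: the
#'   fully null configuration used for error-control studies.
#' @param profile_concentration Dirichlet concentration on a protein's home
#'   peak block (off-block peaks get 0.1).
#' @param complement_threshold Minimum expected composition share for a
#'   disjoint group trait to be listed with a negative expected sign in the
#'   planted truth (see [expected_signatures()]).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_discovery = 344, n_replication = 46,
                             n_proteins = 20, n_background_proteins = 10,
                             glycoform_profiles = NULL,
                             abundance_log_mean = NULL,
                             abundance_log_sd = 0.35,
                             glycan_noise_cv = 0.1,
                             protein_readout_noise_sd = 0.2,
                             planted_links = list(),
                             shared_profile = FALSE,
                             profile_concentration = 5,
                             complement_threshold = 0.05,
                             seed = 1L) {
  if (n_discovery < 3 || n_replication < 3) {
    stop("cohort sizes must be at least 3", call. = FALSE)
  }
  if (glycan_noise_cv < 0 || protein_readout_noise_sd < 0 ||
    any(abundance_log_sd < 0)) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_discovery = as.integer(n_discovery),
      n_replication = as.integer(n_replication),
      n_proteins = as.integer(n_proteins),
      n_background_proteins = as.integer(n_background_proteins),
      glycoform_profiles = glycoform_profiles,
      abundance_log_mean = abundance_log_mean,
      abundance_log_sd = abundance_log_sd,
      glycan_noise_cv = glycan_noise_cv,
      protein_readout_noise_sd = protein_readout_noise_sd,
      planted_links = planted_links,
      shared_profile = shared_profile,
      profile_concentration = profile_concentration,
      complement_threshold = complement_threshold,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Describe a planted protein-glycan link
#'
#' A `source` link makes the protein a major contributor of its dominant
#' peaks: its glycoform profile concentrates `peak_mass` on `peaks` and its
#' abundance gets an elevated spread (`abundance_sd`) so the mixture share of
#' those peaks tracks the protein. An `enzyme` link instead multiplies the
#' designated peak fractions by `abundance^gamma` before renormalization, the
#' signature of a biosynthetic enzyme acting on specific structures.
#'
#' The defaults of a `source` link are calibrated so that, under the default
#' [synthetic_config()], the population correlation between the protein
#' readout and the primary percent trait of its dominant peak is about 0.5
#' on the inverse-normal scale, i.e. a mid-range replicable effect.
#'
#' @param protein Assayed protein id (e.g. `"P01"`).
#' @param peaks Character vector of dominant peak ids (e.g. `"GP24"`).
#' @param type `"source"` or `"enzyme"`.
#' @param sign Expected association direction on the peaks' own traits
#'   (+1 for both built-in mechanisms).
#' @param peak_mass Fraction of the protein's glycoform mass on `peaks`
#'   (source links).
#' @param abundance_sd Log-scale abundance sd of the linked protein.
#' @param mean_log Log-scale mean abundance of the linked protein.
#' @param gamma Enzyme-link exponent.
#' @return A list of class `planted_link`.
#' @export
planted_link <- function(protein, peaks, type = c("source", "enzyme"),
                         sign = 1, peak_mass = 0.85, abundance_sd = 0.28,
                         mean_log = -0.5, gamma = 0.6) {
  type <- match.arg(type)
  structure(
    list(protein = protein, peaks = peaks, type = type, sign = sign,
      peak_mass = peak_mass, abundance_sd = abundance_sd,
      mean_log = mean_log, gamma = gamma),
    class = "planted_link"
  )
}

# Structure-coherent peak blocks used for Dirichlet profile draws: proteins
# tend to carry glycoforms of one sialylation/branching family.
profile_blocks <- function(annotations) {
  dom <- annotations$dominant
  sial <- vapply(dom, function(s) s$sialic_acids, integer(1))
  fam <- vapply(dom, function(s) s$family, "")
  list(
    neutral_complex = annotations$peak_id[sial == 0L & fam == "complex"],
    high_mannose = annotations$peak_id[fam == "high_mannose"],
    monosialylated = annotations$peak_id[sial == 1L],
    disialylated = annotations$peak_id[sial == 2L],
    trisialylated = annotations$peak_id[sial == 3L],
    tetrasialylated = annotations$peak_id[sial == 4L]
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Deterministic materialization of per-protein parameters from the config.
materialize_parameters <- function(config, annotations) {
  peaks <- annotations$peak_id
  n_total <- config$n_proteins + config$n_background_proteins
  assayed <- sprintf("P%02d", seq_len(config$n_proteins))
  background <- if (config$n_background_proteins > 0L) {
    sprintf("B%02d", seq_len(config$n_background_proteins))
  } else {
    character(0)
  }
  ids <- c(assayed, background)

  set.seed(config$seed)
  if (is.null(config$glycoform_profiles)) {
    blocks <- profile_blocks(annotations)
    if (config$shared_profile) {
      base <- rdirichlet1(rep(1, length(peaks)))
      profiles <- matrix(base, n_total, length(peaks), byrow = TRUE)
    } else {
      profiles <- t(vapply(seq_len(n_total), function(i) {
        block <- blocks[[sample.int(length(blocks), 1L)]]
        alpha <- rep(0.1, length(peaks))
        alpha[peaks %in% block] <- config$profile_concentration
        rdirichlet1(alpha)
      }, numeric(length(peaks))))
    }
    dimnames(profiles) <- list(ids, peaks)
  } else {
    profiles <- config$glycoform_profiles
    if (nrow(profiles) != n_total) {
      stop("glycoform_profiles must have one row per protein (assayed + background)",
        call. = FALSE)
    }
    if (is.null(colnames(profiles))) colnames(profiles) <- peaks
    rownames(profiles) <- ids
    sums <- rowSums(profiles)
    if (any(profiles < 0) || any(abs(sums - 1) > 1e-8)) {
      stop("config error: each glycoform profile must lie on the simplex",
        call. = FALSE)
    }
  }

  mu <- config$abundance_log_mean
  if (is.null(mu)) {
    mu <- stats::rnorm(n_total, 0, 0.3)
  }
  mu <- rep_len(mu, n_total)
  sigma <- rep_len(config$abundance_log_sd, n_total)
  names(mu) <- names(sigma) <- ids

  # Planted source links override the linked protein's profile and abundance
  # parameters so it becomes a major, variable contributor of its peaks.
  for (link in config$planted_links) {
    if (!link$protein %in% assayed) {
      stop("planted link references unknown assayed protein: ", link$protein,
        call. = FALSE)
    }
    if (!all(link$peaks %in% peaks)) {
      stop("planted link references unknown peak(s): ",
        paste(setdiff(link$peaks, peaks), collapse = ", "), call. = FALSE)
    }
    if (link$type == "source") {
      prof <- rep(0.0, length(peaks))
      names(prof) <- peaks
      prof[link$peaks] <- link$peak_mass / length(link$peaks)
      rest <- rdirichlet1(rep(0.5, length(peaks)))
      prof <- prof + (1 - link$peak_mass) * rest
      prof <- prof / sum(prof)
      profiles[link$protein, ] <- prof
    }
    mu[link$protein] <- link$mean_log
    sigma[link$protein] <- link$abundance_sd
  }

  cohort_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  list(profiles = profiles, mu = mu, sigma = sigma, assayed = assayed,
    background = background, cohort_seeds = cohort_seeds)
}

draw_cohort <- function(config, params, n, sub_seed, id_prefix) {
  set.seed(sub_seed)
  peaks <- colnames(params$profiles)
  ids <- c(params$assayed, params$background)
  sample_ids <- sprintf("%s%04d", id_prefix, seq_len(n))

  sdlog <- sqrt(log(1 + config$glycan_noise_cv^2))
  for (attempt in seq_len(100L)) {
    A <- exp(matrix(stats::rnorm(n * length(ids)), n, length(ids)) %*%
      diag(params$sigma, length(ids)) +
      matrix(params$mu, n, length(ids), byrow = TRUE))
    colnames(A) <- ids
    G <- A %*% params$profiles
    for (link in config$planted_links) {
      if (link$type == "enzyme") {
        G[, link$peaks] <- G[, link$peaks] * A[, link$protein]^link$gamma
      }
    }
    if (sdlog > 0) {
      G <- G * exp(matrix(stats::rnorm(n * length(peaks), 0, sdlog), n, length(peaks)))
    }
    totals <- rowSums(G)
    if (all(totals > 0)) break
    if (attempt == 100L) {
      stop("failed to generate a non-degenerate cohort after 100 attempts",
        call. = FALSE)
    }
  }
  peak_pct <- sweep(G, 1L, totals, "/") * 100
  readout <- log(A[, params$assayed, drop = FALSE])
  if (config$protein_readout_noise_sd > 0) {
    readout <- readout + matrix(
      stats::rnorm(length(readout), 0, config$protein_readout_noise_sd),
      nrow(readout), ncol(readout))
  }
  rownames(peak_pct) <- rownames(readout) <- sample_ids
  list(proteins = readout, peaks = peak_pct)
}

#' Generate paired discovery and replication cohorts with planted truth
#'
#' Draws both cohorts from identical protein parameters (profiles, abundance
#' distributions, links) with independent sub-seeds derived from
#' `config$seed`; the run is bit-reproducible for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param catalog Trait catalog used to propagate planted peaks to affected
#'   trait ids in the returned truth.
#' @param annotations A `peak_annotation`.
#' @return A list with elements `discovery` and `replication` (each a list
#'   with `proteins`, a samples x assayed-proteins log-readout matrix, and
#'   `peaks`, a samples x 36 percent matrix whose rows sum to 100), `truth`
#'   (see [expected_signatures()]) and `params` (the materialized
#'   per-protein profiles and abundance parameters).
#' @export
generate_cohorts <- function(config, catalog = builtin_catalog(),
                             annotations = builtin_peak_annotations()) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- materialize_parameters(config, annotations)
  discovery <- draw_cohort(config, params, config$n_discovery,
    params$cohort_seeds[1], "D")
  replication <- draw_cohort(config, params, config$n_replication,
    params$cohort_seeds[2], "R")
  truth <- expected_signatures(config, catalog, annotations)
  list(discovery = discovery, replication = replication, truth = truth,
    params = params)
}

#' Expected association signatures of the planted links
#'
#' Propagates each planted link through the trait catalog: the link's
#' protein is expected to associate positively with the primary percent
#' traits of its peaks and with every group/sub-fraction trait whose
#' numerator overlaps them, and negatively with the compositional
#' complements - group traits over the total composition whose peak sets are
#' disjoint from the link peaks and whose expected mixture share exceeds
#' `config$complement_threshold` (small complements are too weak to call),
#' plus neutral-subprofile traits disjoint from the link peaks whenever the
#' link touches the neutral subcomposition at all.
#'
#' @param config A [synthetic_config()].
#' @param catalog A `trait_catalog`.
#' @param annotations A `peak_annotation`.
#' @return Data frame of class `synthetic_truth` with columns `protein_id`,
#'   `trait_id`, `expected_sign`; empty when no links are planted.
#' @export
expected_signatures <- function(config, catalog = builtin_catalog(),
                                annotations = builtin_peak_annotations()) {
  stopifnot(inherits(config, "synthetic_config"))
  empty <- data.frame(protein_id = character(0), trait_id = character(0),
    expected_sign = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("synthetic_truth", "data.frame")
  if (length(config$planted_links) == 0L) {
    return(empty)
  }
  params <- materialize_parameters(config, annotations)
  # Expected raw composition of the mixture (used to size complements).
  mean_abund <- exp(params$mu + params$sigma^2 / 2)
  expected_peak <- colSums(params$profiles * mean_abund)
  expected_share <- expected_peak / sum(expected_peak)
  neutral <- neutral_peaks(annotations)

  rows <- list()
  for (link in config$planted_links) {
    for (t in catalog$traits) {
      if (t$kind == "ratio") next
      sets <- resolve_trait_peaks(t, annotations)
      overlaps <- length(intersect(sets$numerator, link$peaks)) > 0L
      if (overlaps) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = link$protein, trait_id = t$trait_id,
          expected_sign = as.integer(link$sign), stringsAsFactors = FALSE)
        next
      }
      disjoint_num <- length(sets$numerator) > 0L
      if (!disjoint_num) next
      if (t$kind == "group_percent" && t$denominator == "total") {
        if (sum(expected_share[sets$numerator]) >= config$complement_threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = link$protein, trait_id = t$trait_id,
            expected_sign = -as.integer(link$sign), stringsAsFactors = FALSE)
        }
      } else if (t$denominator == "neutral_total" &&
        length(intersect(link$peaks, neutral)) > 0L) {
        share_neutral <- sum(expected_peak[sets$numerator]) /
          sum(expected_peak[neutral])
        if (share_neutral >= config$complement_threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = link$protein, trait_id = t$trait_id,
            expected_sign = -as.integer(link$sign), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synthetic_truth", "data.frame")
  out
}
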