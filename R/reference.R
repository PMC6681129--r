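#' Previously reported protein-glycan correlations
#'
#' A curated table of previously reported Pearson correlations between plasma
#' protein levels and plasma N-glycan traits in a 344-sample discovery cohort
#' and a 46-sample replication cohort (inverse-normal scaled on both layers),
#' covering the strongest replicated associations: IgG with core-fucosylated
#' and neutral biantennary traits, IgM/CD5L with bisected monosialylated
#' structures, heparin cofactor 2 with trisialylated/triantennary traits,
#' FUT5 with tetraantennary and antennary-fucosylated traits, CRP with
#' trisialylated structures, and FCGR3B with A2(6)BG1.
#'
#' Used as a sanity fixture: the printed p-values should be recoverable from
#' the printed correlations and sample sizes via the Pearson t-test (to
#' within the rounding of a 2-decimal correlation), and the two cohorts'
#' effect directions should be fully concordant.
#'
#' @return Data frame with columns `protein`, `trait_id`, `trait_name`,
#'   `r_discovery`, `r_replication`, `p_discovery`, `p_replication`,
#'   `n_discovery`, `n_replication`.
#' @export
published_associations <- function() {
  path <- system.file("extdata", "published_associations.tsv",
    package = "glycoproteomap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
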