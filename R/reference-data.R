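#' Published JADER angioedema reference counts
#'
#' Case counts and BCPNN scores from a published disproportionality
#' analysis of angioedema (SMQ 20000024, narrow plus broad scope) against
#' ACE-inhibitor and DPP-4-inhibitor exposures in the JADER database
#' (October 2019 release; 534,287 retained cases). Per drug and per class:
#' the angioedema case count `n11`, the drug margin `n1plus`, and the
#' published IC with its 95 percent credible bounds (`NA` where the source
#' table printed a dash). The event margin N+1 was not published; recover
#' it with [calibrate_margin()].
#'
#' These counts serve as golden values for validating the estimator and as
#' realistic scale anchors for [jader_like_config()].
#'
#' @return A list with elements `counts` (per-drug data frame), `strata`
#'   (sex/age stratified counts with reporting rates) and `n_total`
#'   (534287).
#' @examples
#' ref <- angioedema_reference()
#' head(ref$counts)
#' @export
angioedema_reference <- function() {
  counts <- read.delim(system.file("extdata", "jader_angioedema_counts.tsv",
                                   package = "pvsignal"),
                       stringsAsFactors = FALSE)
  strata <- read.delim(system.file("extdata", "jader_angioedema_strata.tsv",
                                   package = "pvsignal"),
                       stringsAsFactors = FALSE)
  list(counts = counts, strata = strata, n_total = 534287L)
}

#' Bundled drug-class membership lists
#'
#' The 12 ACE inhibitors and 9 DPP-4 inhibitors marketed in Japan that the
#' reference analysis investigated.
#'
#' @return A named list of two [drug_group()]s: `ace` and `dpp4`.
#' @export
reference_drug_classes <- function() {
  list(ace = read_drug_list(system.file("extdata", "ace_inhibitors.txt",
                                        package = "pvsignal"),
                            name = "ACE inhibitors"),
       dpp4 = read_drug_list(system.file("extdata", "dpp4_inhibitors.txt",
                                         package = "pvsignal"),
                             name = "DPP-4 inhibitors"))
}

#' A reporting-database config at the reference study's scale
#'
#' Builds a [synthetic_config()] emulating the reference JADER analysis at
#' a chosen scale: the two drug classes with their real member names,
#' per-drug exposure probabilities matched to the published margins
#' `n1plus / 534287`, per-drug reporting ratios set to `2^IC` of the
#' published scores (null for dash/zero rows), twenty background drugs
#' carrying the rest of the event margin, and demographics shaped like the
#' published strata. The baseline event probability is solved numerically
#' so the expected event prevalence matches the calibrated margin fraction
#' `10802 / 534287`.
#'
#' @param scale Fraction of the study's 534,287 cases to simulate; default
#'   `0.1` (about 53,000 cases).
#' @param seed Default seed stored in the config.
#' @return A [synthetic_config()].
#' @export
jader_like_config <- function(scale = 0.1, seed = 1L) {
  ref <- angioedema_reference()
  drugs <- ref$counts[ref$counts$drug != "(class)", , drop = FALSE]
  lambda <- ifelse(is.na(drugs$ic) | drugs$n11 == 0, 1, 2^drugs$ic)
  spec <- data.frame(drug = drugs$drug,
                     exposure_prob = drugs$n1plus / ref$n_total,
                     lambda = lambda,
                     class = drugs$class,
                     stringsAsFactors = FALSE)
  bg <- data.frame(drug = sprintf("backgrounddrug%02d", 1:20),
                   exposure_prob = 0.08, lambda = 1,
                   class = NA_character_, stringsAsFactors = FALSE)
  spec <- rbind(spec, bg)
  # choose p0 so the model's event prevalence matches the study's margin
  target <- 10802 / ref$n_total
  prev <- function(p0) {
    1 - (1 - p0) * prod(1 - spec$exposure_prob *
                          (p0 * (spec$lambda - 1))) - target
  }
  p0 <- stats::uniroot(prev, c(1e-6, 0.5), tol = 1e-12)$root
  synthetic_config(
    n_cases = max(100L, round(ref$n_total * scale)),
    drug_specs = spec,
    baseline_event_prob = p0,
    exclusion_noise = c(subjective_age = 0.01, missing_sex = 0.005,
                        missing_age = 0.01),
    seed = seed)
}
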