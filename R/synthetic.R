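#' Configure a synthetic spontaneous-reporting database
#'
#' Defines the generative model behind [simulate_reports()]: per-case
#' demographics, independent Bernoulli drug exposures, and an event that
#' occurs with probability
#' `1 - (1 - p0) * prod_d exposed (1 - p0 * (lambda_d - 1))` —
#' a case-level baseline hazard `p0` composed independently with one
#' excess-hazard factor per exposed drug. The reporting ratio `lambda_d`
#' is the per-drug risk ratio in the small-`p0` limit: a `lambda = 1` drug
#' is exactly null (its users report the event at the background rate, so
#' its asymptotic information component is 0 bits regardless of what else
#' is in the database), `lambda = 4` gives an asymptotic IC near
#' `log2 4 = 2` bits, and `lambda < 1` under-reports. Requires
#' `lambda < 1 + 1/p0` so every factor stays positive.
#'
#' @param n_cases Number of cases to generate.
#' @param drug_specs Data frame with columns `drug` (name),
#'   `exposure_prob`, `lambda` (reporting ratio, >= 0) and optionally
#'   `class` (drug-class label, NA for background drugs).
#' @param sex_probs,age_band_probs Named categorical distributions over the
#'   canonical sex and age-band levels; must sum to 1.
#' @param baseline_event_prob Per-exposure baseline event probability `p0`.
#' @param pt_pool Data frame with columns `pt_code`, `scope`
#'   (narrow/broad), `weight`: the SMQ terms given to event cases. Event
#'   cases receive 1-3 distinct terms so case-level deduplication is
#'   exercised.
#' @param co_rx Optional data frame `drug_a`, `drug_b`, `odds_multiplier`
#'   tilting drug_b's exposure odds among drug_a users (co-prescription).
#' @param exclusion_noise Named fractions (`subjective_age`, `missing_sex`,
#'   `missing_age`) of cases whose demographics are corrupted so exclusion
#'   rules have work to do.
#' @param require_exposure Resample cases that drew no drug at all so every
#'   case has at least one exposure. Off by default (keeps the closed-form
#'   expectations of [truth_table()] exact).
#' @param seed Default seed used by [simulate_reports()].
#' @param year_range Inclusive report-year range.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases,
                             drug_specs,
                             sex_probs = c(female = 0.48, male = 0.52),
                             age_band_probs = c("<40" = 0.15, "40-49" = 0.10,
                                                "50-59" = 0.13, "60-69" = 0.20,
                                                "70-79" = 0.23, "80-89" = 0.15,
                                                ">=90" = 0.04),
                             baseline_event_prob = 0.02,
                             pt_pool = default_pt_pool(),
                             co_rx = NULL,
                             exclusion_noise = c(subjective_age = 0,
                                                 missing_sex = 0,
                                                 missing_age = 0),
                             require_exposure = FALSE,
                             seed = 1L,
                             year_range = c(2010, 2019)) {
  stopifnot(n_cases >= 1,
            all(c("drug", "exposure_prob", "lambda") %in% names(drug_specs)),
            baseline_event_prob > 0, baseline_event_prob < 1,
            all(drug_specs$exposure_prob >= 0),
            all(drug_specs$exposure_prob <= 1),
            all(drug_specs$lambda >= 0),
            all(drug_specs$lambda < 1 + 1 / baseline_event_prob))
  if (abs(sum(sex_probs) - 1) > 1e-8 || abs(sum(age_band_probs) - 1) > 1e-8)
    stop("sex_probs and age_band_probs must each sum to 1")
  if (!"class" %in% names(drug_specs)) drug_specs$class <- NA_character_
  drug_specs$drug <- normalize_drug_name(drug_specs$drug)
  if (anyDuplicated(drug_specs$drug)) stop("duplicate drugs in drug_specs")
  noise <- c(subjective_age = 0, missing_sex = 0, missing_age = 0)
  noise[names(exclusion_noise)] <- exclusion_noise
  if (sum(noise) >= 1) stop("exclusion_noise fractions must sum below 1")
  structure(list(n_cases = as.integer(n_cases), drug_specs = drug_specs,
                 sex_probs = sex_probs, age_band_probs = age_band_probs,
                 baseline_event_prob = baseline_event_prob,
                 pt_pool = pt_pool, co_rx = co_rx,
                 exclusion_noise = noise,
                 require_exposure = require_exposure,
                 seed = as.integer(seed), year_range = year_range),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic reporting-database config:", x$n_cases, "cases,",
      nrow(x$drug_specs), "drugs, p0 =", x$baseline_event_prob, "\n")
  invisible(x)
}

#' Default synthetic SMQ term pool
#'
#' Five synthetic preferred-term codes (three narrow, two broad) with
#' unequal selection weights. Matches the bundled
#' `smq_angioedema_synthetic.tsv` fixture.
#'
#' @return Data frame with columns `pt_code`, `scope`, `weight`.
#' @export
default_pt_pool <- function() {
  data.frame(pt_code = c("PT900001", "PT900002", "PT900003",
                         "PT900004", "PT900005"),
             scope = c("narrow", "narrow", "narrow", "broad", "broad"),
             weight = c(5, 3, 1, 2, 1),
             stringsAsFactors = FALSE)
}

#' SMQ definition matching a synthetic config's term pool
#'
#' @param config A [synthetic_config()].
#' @param smq_id Code given to the synthetic SMQ.
#' @return An [smq_definition()] covering the config's `pt_pool`.
#' @export
smq_for_config <- function(config, smq_id = "90000001") {
  smq_definition(smq_id, config$pt_pool$pt_code, config$pt_pool$scope,
                 name = "synthetic angioedema-like SMQ")
}

#' Drug-class groups declared in a synthetic config
#'
#' @param config A [synthetic_config()].
#' @return Named list of [drug_group()]s, one per distinct non-NA `class`
#'   label in `drug_specs`.
#' @export
config_groups <- function(config) {
  cls <- unique(stats::na.omit(config$drug_specs$class))
  setNames(lapply(cls, function(cl) {
    drug_group(cl, config$drug_specs$drug[
      !is.na(config$drug_specs$class) & config$drug_specs$class == cl])
  }), cls)
}

#' Generate a synthetic four-table report database
#'
#' Samples cases from the generative model of [synthetic_config()] and
#' returns them as a `case_db` (write with [write_report_tables()] for the
#' on-disk four-table layout). The same config and seed always produce an
#' identical database.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to the config's.
#' @return A `case_db` with attribute `"seed"`.
#' @export
simulate_reports <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_cases
  ds <- config$drug_specs
  d <- nrow(ds)
  p0 <- config$baseline_event_prob

  case_id <- sprintf("SYN-%07d", seq_len(n))
  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  age <- sample(names(config$age_band_probs), n, TRUE,
                config$age_band_probs)
  year <- sample(seq(config$year_range[1], config$year_range[2]), n, TRUE)

  expo <- matrix(stats::runif(n * d), n, d) <
    matrix(ds$exposure_prob, n, d, byrow = TRUE)
  if (!is.null(config$co_rx)) {
    for (k in seq_len(nrow(config$co_rx))) {
      a <- match(normalize_drug_name(config$co_rx$drug_a[k]), ds$drug)
      b <- match(normalize_drug_name(config$co_rx$drug_b[k]), ds$drug)
      m <- config$co_rx$odds_multiplier[k]
      if (is.na(a) || is.na(b)) stop("co_rx names an unknown drug")
      pb <- ds$exposure_prob[b]
      pb_tilt <- m * pb / (1 - pb + m * pb)  # odds multiplied by m
      on_a <- which(expo[, a])
      expo[on_a, b] <- stats::runif(length(on_a)) < pb_tilt
    }
  }
  if (config$require_exposure) {
    none <- which(rowSums(expo) == 0L)
    for (it in seq_len(100)) {
      if (!length(none)) break
      expo[none, ] <- matrix(stats::runif(length(none) * d),
                             length(none), d) <
        matrix(ds$exposure_prob, length(none), d, byrow = TRUE)
      none <- none[rowSums(expo[none, , drop = FALSE]) == 0L]
    }
    if (length(none))  # give up resampling, assign one drug by prevalence
      expo[cbind(none, sample(d, length(none), TRUE,
                              ds$exposure_prob + 1e-12))] <- TRUE
  }

  # case-level baseline hazard composed with per-drug excess hazards;
  # a lambda = 1 drug contributes a unit factor, i.e. nothing
  excess <- pmin(p0 * (ds$lambda - 1), 1 - 1e-12)
  log_q <- log1p(-excess)
  p_event <- pmax(1 - (1 - p0) * exp(as.vector(expo %*% log_q)), 0)
  capped <- p_event > 0.99
  if (any(capped)) {
    warning(sum(capped), " case(s) hit the 0.99 event-probability cap")
    p_event[capped] <- 0.99
  }
  event <- stats::runif(n) < p_event

  # REAC rows: every case reports one background term; event cases add
  # 1-3 distinct SMQ terms (duplicates within a case are impossible by
  # construction, matching the set semantics of case_db)
  bg_pt <- paste0("PTBG", sprintf("%04d", sample(50, n, TRUE)))
  reac <- data.frame(case_id = case_id, pt = bg_pt,
                     stringsAsFactors = FALSE)
  ev_idx <- which(event)
  if (length(ev_idx)) {
    k <- sample(1:3, length(ev_idx), TRUE, prob = c(0.6, 0.3, 0.1))
    pool <- config$pt_pool
    picks <- lapply(k, function(ki)
      sample(pool$pt_code, min(ki, nrow(pool)), FALSE, pool$weight))
    reac <- rbind(reac, data.frame(
      case_id = rep(case_id[ev_idx], lengths(picks)),
      pt = unlist(picks), stringsAsFactors = FALSE))
  }

  which_expo <- which(expo, arr.ind = TRUE)
  drug <- data.frame(case_id = case_id[which_expo[, 1]],
                     drug_name = ds$drug[which_expo[, 2]],
                     role = "suspected", stringsAsFactors = FALSE)
  drug <- drug[order(which_expo[, 1], which_expo[, 2]), , drop = FALSE]

  # corrupt demographics of disjoint random subsets
  noise <- config$exclusion_noise
  n_noise <- round(noise * n)
  corrupt <- sample(n, sum(n_noise))
  i_subj <- corrupt[seq_len(n_noise["subjective_age"])]
  i_sex <- corrupt[seq_len(n_noise["missing_sex"]) +
                     n_noise["subjective_age"]]
  i_age <- corrupt[seq_len(n_noise["missing_age"]) +
                     n_noise["subjective_age"] + n_noise["missing_sex"]]
  age[i_subj] <- "elderly"
  sex[i_sex] <- ""
  age[i_age] <- ""

  demo <- data.frame(case_id = case_id, sex = sex, age = age,
                     report_year = year, stringsAsFactors = FALSE)
  db <- case_db(demo, drug, reac)
  attr(db, "seed") <- seed
  db
}

#' Closed-form expectations under a synthetic config
#'
#' For each drug with `lambda != 1` (and each declared class), the expected
#' contingency counts among retained cases and the asymptotic information
#' component `log2(P(event | exposed) / P(event))` implied by the
#' generative model. Exact for independent exposures (the defaults);
#' `co_rx` tilting and `require_exposure` resampling make it approximate,
#' so a warning is issued when either is set.
#'
#' @param config A [synthetic_config()].
#' @param drugs Group names to report on: drug names or declared class
#'   labels. Default: all drugs with `lambda != 1` plus every class group.
#' @return Data frame with columns `group`, `e_n11`, `e_n1plus`,
#'   `e_nplus1`, `e_nplusplus`, `asymptotic_ic`.
#' @export
truth_table <- function(config, drugs = NULL) {
  if (!is.null(config$co_rx) || config$require_exposure)
    warning("expectations are approximate with co_rx or require_exposure")
  ds <- config$drug_specs
  p0 <- config$baseline_event_prob
  ex <- pmin(p0 * (ds$lambda - 1), 1 - 1e-12)  # per-drug excess hazard
  q <- 1 - ds$exposure_prob * ex               # per-drug survival factor
  p_event <- 1 - (1 - p0) * prod(q)
  retain <- 1 - sum(config$exclusion_noise)
  n_ret <- config$n_cases * retain

  one <- function(members, label) {
    in_g <- ds$drug %in% members
    if (!any(in_g)) stop("unknown drug or class '", label, "'")
    p_exp <- 1 - prod(1 - ds$exposure_prob[in_g])
    if (sum(in_g) == 1L) {
      p_e_exp <- 1 - (1 - p0) * (1 - ex[in_g]) * prod(q[!in_g])
    } else {
      # average over member exposure patterns, conditioned on >= 1 member
      pats <- expand.grid(rep(list(c(FALSE, TRUE)), sum(in_g)))
      w <- apply(pats, 1, function(z)
        prod(ifelse(z, ds$exposure_prob[in_g], 1 - ds$exposure_prob[in_g])))
      pe <- apply(pats, 1, function(z)
        1 - (1 - p0) * prod((1 - ex[in_g])[as.logical(z)]) * prod(q[!in_g]))
      keep <- rowSums(pats) > 0
      p_e_exp <- sum(w[keep] * pe[keep]) / sum(w[keep])
    }
    data.frame(group = label,
               e_n11 = n_ret * p_exp * p_e_exp,
               e_n1plus = n_ret * p_exp,
               e_nplus1 = n_ret * p_event,
               e_nplusplus = n_ret,
               asymptotic_ic = log2(p_e_exp / p_event),
               stringsAsFactors = FALSE)
  }

  cls <- unique(stats::na.omit(ds$class))
  if (is.null(drugs))
    drugs <- c(ds$drug[ds$lambda != 1], cls)
  rows <- lapply(drugs, function(dr) {
    if (dr %in% cls)
      one(ds$drug[!is.na(ds$class) & ds$class == dr], dr)
    else one(dr, dr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
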