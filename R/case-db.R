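#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv head
NULL

# canonical levels used throughout
.sex_levels <- c("female", "male", "missing")
.age_levels <- c("<40", "40-49", "50-59", "60-69", "70-79", "80-89", ">=90",
                 "subjective", "missing")
.role_levels <- c("suspected", "concomitant", "interacting", "unknown")

#' Canonical column mapping for the four-table layout
#'
#' Spontaneous-report databases in the JADER style ship as four linked CSV
#' tables: DEMO (one row per case: demographics), DRUG (one row per drug
#' exposure), REAC (one row per reported adverse-event preferred term) and
#' HIST (medical history; read but unused by the analysis). Physical column
#' names vary between releases and translations, so readers resolve logical
#' columns through a mapping. `default_column_map()` is the English
#' canonical schema; override entries to match other headers, e.g.
#' `default_column_map(demo = c(case_id = "ID"))`.
#'
#' @param demo,drug,reac,hist Named character vectors overriding entries of
#'   the canonical map for one table; names are logical columns, values the
#'   physical header names.
#' @return A named list of four named character vectors (logical ->
#'   physical) for the `demo`, `drug`, `reac` and `hist` tables.
#' @export
default_column_map <- function(demo = NULL, drug = NULL, reac = NULL,
                               hist = NULL) {
  map <- list(
    demo = c(case_id = "case_id", sex = "sex", age = "age",
             report_year = "report_year"),
    drug = c(case_id = "case_id", drug_name = "drug_name", role = "role"),
    reac = c(case_id = "case_id", pt = "pt"),
    hist = c(case_id = "case_id", condition = "condition"))
  for (tab in c("demo", "drug", "reac", "hist")) {
    ov <- get(tab)
    if (!is.null(ov)) map[[tab]][names(ov)] <- ov
  }
  map
}

.resolve_columns <- function(df, map, table_name, required) {
  for (logical_col in required) {
    phys <- map[[logical_col]]
    if (is.na(phys) || !phys %in% names(df))
      stop("table '", table_name, "' is missing the physical column '",
           phys, "' for required logical column '", logical_col, "'")
  }
  out <- df[, unname(map[required]), drop = FALSE]
  names(out) <- required
  out
}

# normalize free-text age into a canonical band; anything non-numeric that
# is not a recognized band or an explicit missing marker counts as a
# subjective term ("youth", "elderly", ...)
.parse_age_band <- function(age) {
  a <- tolower(trimws(as.character(age)))
  a[is.na(a)] <- ""
  out <- rep(NA_character_, length(a))
  out[a %in% c("", "na", "missing", "unknown")] <- "missing"
  a2 <- gsub("–", "-", a)            # en-dash band variants
  a2[a2 %in% c("90-", "≥90", "90+")] <- ">=90"
  idx <- is.na(out) & a2 %in% .age_levels
  out[idx] <- a2[idx]
  idx <- is.na(out) & grepl("^[0-9]+s$", a)  # decade shorthand "60s"
  out[idx] <- .band_from_numeric(as.numeric(sub("s$", "", a[idx])))
  num <- suppressWarnings(as.numeric(a))
  idx <- is.na(out) & !is.na(num)
  out[idx] <- .band_from_numeric(num[idx])
  out[is.na(out)] <- "subjective"
  out
}

.band_from_numeric <- function(x) {
  ifelse(x < 40, "<40",
         ifelse(x >= 90, ">=90",
                paste0(floor(x / 10) * 10, "-", floor(x / 10) * 10 + 9)))
}

.parse_sex <- function(sex) {
  sex <- tolower(trimws(as.character(sex)))
  out <- rep("missing", length(sex))
  out[sex %in% c("female", "f", "woman")] <- "female"
  out[sex %in% c("male", "m", "man")] <- "male"
  out
}

.parse_role <- function(role) {
  role <- tolower(trimws(as.character(role)))
  out <- rep("unknown", length(role))
  out[role %in% .role_levels] <- role[role %in% .role_levels]
  out
}

#' Normalize a drug name to its canonical form
#'
#' Lower-cased, trimmed, internal whitespace collapsed. All matching of
#' drug names against group membership lists happens on this form.
#'
#' @param x Character vector of drug names.
#' @return Character vector of canonical names.
#' @export
normalize_drug_name <- function(x) {
  gsub("[ \t]+", " ", tolower(trimws(as.character(x))))
}

#' Assemble a case-level report database from the four tables
#'
#' Reads the DEMO/DRUG/REAC (and optionally HIST) CSV tables and merges
#' them into a `case_db`: one deduplicated case per distinct case id, with
#' its demographics, drug exposures and the *set* of reported preferred
#' terms (a PT registered several times for one case is kept once, so that
#' downstream counting is by cases, not drug-event combinations).
#'
#' Conflicting demographics across duplicate DEMO rows for one case id are
#' resolved first-occurrence-wins with a warning.
#'
#' @param demo_path,drug_path,reac_path Paths to the three required CSVs
#'   (header row required).
#' @param hist_path Optional path to the history table; stored, unused.
#' @param column_map A [default_column_map()]-style mapping.
#' @param encoding File encoding; `"UTF-8"` default, use `"CP932"` for
#'   Japanese-encoded releases.
#' @return An object of class `case_db`: a list with data frames `demo`
#'   (case_id, sex, age_band, report_year), `drug` (case_id, drug_name,
#'   role), `reac` (case_id, pt) and `hist` (possibly empty).
#' @export
read_report_tables <- function(demo_path, drug_path, reac_path,
                               hist_path = NULL,
                               column_map = default_column_map(),
                               encoding = "UTF-8") {
  rd <- function(p) read.csv(p, stringsAsFactors = FALSE,
                             colClasses = "character",
                             fileEncoding = encoding)
  demo <- .resolve_columns(rd(demo_path), column_map$demo, "demo",
                           c("case_id", "sex", "age", "report_year"))
  drug <- .resolve_columns(rd(drug_path), column_map$drug, "drug",
                           c("case_id", "drug_name", "role"))
  reac <- .resolve_columns(rd(reac_path), column_map$reac, "reac",
                           c("case_id", "pt"))
  hist <- if (!is.null(hist_path))
    .resolve_columns(rd(hist_path), column_map$hist, "hist",
                     c("case_id", "condition"))
  else data.frame(case_id = character(), condition = character(),
                  stringsAsFactors = FALSE)
  case_db(demo, drug, reac, hist)
}

#' Construct a case database from in-memory tables
#'
#' @param demo Data frame with columns `case_id`, `sex`, `age` (or
#'   `age_band`), `report_year`.
#' @param drug Data frame with columns `case_id`, `drug_name`, `role`.
#' @param reac Data frame with columns `case_id`, `pt`.
#' @param hist Optional data frame with columns `case_id`, `condition`.
#' @return A `case_db` object; see [read_report_tables()].
#' @export
case_db <- function(demo, drug, reac, hist = NULL) {
  if (any(!nzchar(demo$case_id)) || anyNA(demo$case_id))
    stop("case_id must be non-empty")
  dup <- duplicated(demo$case_id)
  if (any(dup)) {
    first <- demo[!dup, , drop = FALSE]
    conflicting <- unique(demo$case_id[dup])
    for (id in conflicting) {
      rows <- demo[demo$case_id == id, , drop = FALSE]
      if (nrow(unique(rows[setdiff(names(rows), "case_id")])) > 1L)
        warning("conflicting demographics for case '", id,
                "'; first occurrence wins")
    }
    demo <- first
  }
  age_col <- if ("age_band" %in% names(demo)) demo$age_band else demo$age
  demo_out <- data.frame(
    case_id = demo$case_id,
    sex = .parse_sex(demo$sex),
    age_band = .parse_age_band(age_col),
    report_year = suppressWarnings(as.integer(demo$report_year)),
    stringsAsFactors = FALSE)

  drug <- drug[drug$case_id %in% demo_out$case_id, , drop = FALSE]
  drug_out <- data.frame(
    case_id = drug$case_id,
    drug_name = normalize_drug_name(drug$drug_name),
    role = .parse_role(drug$role),
    stringsAsFactors = FALSE)
  drug_out <- drug_out[nzchar(drug_out$drug_name), , drop = FALSE]

  reac <- reac[reac$case_id %in% demo_out$case_id, , drop = FALSE]
  reac_out <- data.frame(case_id = reac$case_id,
                         pt = trimws(as.character(reac$pt)),
                         stringsAsFactors = FALSE)
  reac_out <- reac_out[nzchar(reac_out$pt), , drop = FALSE]
  reac_out <- reac_out[!duplicated(reac_out[c("case_id", "pt")]), ,
                       drop = FALSE]

  if (is.null(hist))
    hist <- data.frame(case_id = character(), condition = character(),
                       stringsAsFactors = FALSE)
  rownames(demo_out) <- rownames(drug_out) <- rownames(reac_out) <- NULL
  structure(list(demo = demo_out, drug = drug_out, reac = reac_out,
                 hist = hist),
            class = "case_db")
}

#' @export
print.case_db <- function(x, ...) {
  cat("Case-level report database:", nrow(x$demo), "cases,",
      nrow(x$drug), "drug exposures,", nrow(x$reac),
      "event terms\n")
  invisible(x)
}

#' Number of cases in a database
#' @param db A `case_db`.
#' @return Integer case count.
#' @export
n_cases <- function(db) nrow(db$demo)

#' Write a case database back to the four-table CSV layout
#'
#' Emits DEMO/DRUG/REAC/HIST CSVs that [read_report_tables()] reads back
#' losslessly for all modeled fields.
#'
#' @param db A `case_db`.
#' @param dir Output directory (created if needed).
#' @param column_map A [default_column_map()]-style mapping used to rename
#'   logical columns back to physical headers.
#' @return Invisibly, the named character vector of the four file paths.
#' @export
write_report_tables <- function(db, dir,
                                column_map = default_column_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rename <- function(df, map) {
    keep <- intersect(names(map), names(df))
    out <- df[, keep, drop = FALSE]
    names(out) <- unname(map[keep])
    out
  }
  demo <- db$demo
  names(demo)[names(demo) == "age_band"] <- "age"
  paths <- c(demo = file.path(dir, "DEMO.csv"),
             drug = file.path(dir, "DRUG.csv"),
             reac = file.path(dir, "REAC.csv"),
             hist = file.path(dir, "HIST.csv"))
  write.csv(rename(demo, column_map$demo), paths["demo"], row.names = FALSE)
  write.csv(rename(db$drug, column_map$drug), paths["drug"],
            row.names = FALSE)
  write.csv(rename(db$reac, column_map$reac), paths["reac"],
            row.names = FALSE)
  write.csv(rename(db$hist, column_map$hist), paths["hist"],
            row.names = FALSE)
  invisible(paths)
}

#' Case-exclusion rules
#'
#' Cases whose age uses subjective terms (such as "youth" or "elderly"), or
#' that lack sex or age information, are conventionally excluded before
#' disproportionality analysis. All three rules default to on.
#'
#' @param drop_subjective_age,drop_missing_sex,drop_missing_age Logical
#'   flags for the three rules.
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(drop_subjective_age = TRUE,
                            drop_missing_sex = TRUE,
                            drop_missing_age = TRUE) {
  structure(list(drop_subjective_age = drop_subjective_age,
                 drop_missing_sex = drop_missing_sex,
                 drop_missing_age = drop_missing_age),
            class = "exclusion_rules")
}

#' Apply exclusion rules to a case database
#'
#' Removes cases violating any active rule; each removed case is tallied
#' under its *first* matching reason, in the order subjective age, missing
#' sex, missing age, so the counts partition the removed cases. The number
#' retained is the analysis-wide database total N++.
#'
#' @param db A `case_db`.
#' @param rules An [exclusion_rules()] object.
#' @return A list with `db` (the retained `case_db`) and `excluded`, a
#'   named integer vector of counts by reason.
#' @export
apply_exclusions <- function(db, rules = exclusion_rules()) {
  # first matching reason wins, in the order subjective_age, missing_sex,
  # missing_age, so the counts partition the removed cases
  reason <- rep(NA_character_, n_cases(db))
  if (rules$drop_subjective_age)
    reason[db$demo$age_band == "subjective"] <- "subjective_age"
  if (rules$drop_missing_sex)
    reason[is.na(reason) & db$demo$sex == "missing"] <- "missing_sex"
  if (rules$drop_missing_age)
    reason[is.na(reason) & db$demo$age_band == "missing"] <- "missing_age"
  keep_ids <- db$demo$case_id[is.na(reason)]
  counts <- c(subjective_age = sum(reason == "subjective_age", na.rm = TRUE),
              missing_sex = sum(reason == "missing_sex", na.rm = TRUE),
              missing_age = sum(reason == "missing_age", na.rm = TRUE))
  out <- db
  out$demo <- db$demo[is.na(reason), , drop = FALSE]
  out$drug <- db$drug[db$drug$case_id %in% keep_ids, , drop = FALSE]
  out$reac <- db$reac[db$reac$case_id %in% keep_ids, , drop = FALSE]
  out$hist <- db$hist[db$hist$case_id %in% keep_ids, , drop = FALSE]
  rownames(out$demo) <- rownames(out$drug) <- rownames(out$reac) <- NULL
  list(db = out, excluded = counts)
}
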