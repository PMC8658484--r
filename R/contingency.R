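#' Define a drug or drug-class group
#'
#' A group is a named, non-empty set of normalized generic drug names. A
#' singleton group represents an individual drug; a class group (e.g. the
#' ACE inhibitors) lists all member drugs. Counting against a group is
#' case-based: a case exposed to several members still counts once.
#'
#' @param name Group label.
#' @param members Character vector of generic drug names (normalized with
#'   [normalize_drug_name()]).
#' @return An object of class `drug_group`.
#' @examples
#' drug_group("ACE inhibitors", c("enalapril", "imidapril"))
#' @export
drug_group <- function(name, members) {
  members <- unique(normalize_drug_name(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("drug group '", name, "' has no members")
  structure(list(name = name, members = members), class = "drug_group")
}

#' @export
print.drug_group <- function(x, ...) {
  cat("Drug group '", x$name, "': ", length(x$members), " member",
      if (length(x$members) != 1) "s", "\n", sep = "")
  invisible(x)
}

#' Read a drug-class membership list
#'
#' Plain-text format: one generic name per line; blank lines and `#`
#' comments ignored.
#'
#' @param path Path to the list file.
#' @param name Group label; defaults to the file name without extension.
#' @return A [drug_group()].
#' @export
read_drug_list <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  drug_group(name, lines)
}

# case ids exposed to >= 1 member of the group with an allowed role
.exposed_ids <- function(db, group, roles) {
  rows <- db$drug$drug_name %in% group$members & db$drug$role %in% roles
  unique(db$drug$case_id[rows])
}

#' Build the case-based 2x2 contingency table for a group
#'
#' Cross-classifies the retained cases by exposure to the group and by the
#' event flag. A case is exposed when it has at least one counted exposure
#' to at least one member drug — counted once even with several member
#' drugs, so class-level counts are deduplicated case counts, not sums over
#' members. The four cells partition the cases.
#'
#' @param db A `case_db` (exclusions already applied).
#' @param group A [drug_group()].
#' @param flags Named logical vector from [flag_cases()] covering all cases.
#' @param roles Drug roles counted as exposure; default `"suspected"` only.
#' @return An object of class `contingency_table`: a list with `group`, the
#'   cells `n11`, `n10`, `n01`, `n00`, and margins `n1plus`, `nplus1`,
#'   `nplusplus`.
#' @export
count_table <- function(db, group, flags, roles = "suspected") {
  if (!inherits(group, "drug_group")) stop("group must be a drug_group")
  ids <- db$demo$case_id
  if (!all(ids %in% names(flags)))
    stop("flags must cover all case ids in the database")
  flag <- unname(flags[ids])
  exposed <- ids %in% .exposed_ids(db, group, roles)
  contingency_table(group$name,
                    n11 = sum(exposed & flag),
                    n10 = sum(exposed & !flag),
                    n01 = sum(!exposed & flag),
                    n00 = sum(!exposed & !flag))
}

#' Construct a 2x2 contingency table from its cells
#'
#' @param group Group label.
#' @param n11,n10,n01,n00 Non-negative integer case counts: target drug and
#'   target event, drug only, event only, neither.
#' @return A `contingency_table` with derived margins.
#' @export
contingency_table <- function(group, n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  structure(list(group = group, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n1plus = n11 + n10, nplus1 = n11 + n01,
                 nplusplus = n11 + n10 + n01 + n00),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 case counts for '", x$group, "':\n", sep = "")
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2, 2,
              dimnames = list(c("group", "other drugs"),
                              c("event", "other events")))
  print(m)
  cat("margins: n1+ =", x$n1plus, ", n+1 =", x$nplus1,
      ", n++ =", x$nplusplus, "\n")
  invisible(x)
}

#' Stratified exposure and event counts
#'
#' Reproduces the layout of published characteristics tables: per stratum
#' (Total, each sex, each decade age band), the number of group-exposed
#' cases with the event (`n11`), all group-exposed cases (`n1plus`), and
#' the reporting rate `100 * n11 / n1plus`.
#'
#' @inheritParams count_table
#' @param by_sex,by_age_band Which stratification axes to include (at least
#'   one; both default on).
#' @return A data frame with columns `stratum`, `n11`, `n1plus`, `rr`.
#' @export
stratify_counts <- function(db, group, flags, roles = "suspected",
                            by_sex = TRUE, by_age_band = TRUE) {
  if (!by_sex && !by_age_band)
    stop("at least one stratification axis is required")
  ids <- db$demo$case_id
  flag <- unname(flags[ids])
  exposed <- ids %in% .exposed_ids(db, group, roles)
  strata <- list(Total = rep(TRUE, length(ids)))
  if (by_sex) {
    strata[["Female"]] <- db$demo$sex == "female"
    strata[["Male"]] <- db$demo$sex == "male"
  }
  if (by_age_band)
    for (b in setdiff(.age_levels, c("subjective", "missing")))
      strata[[b]] <- db$demo$age_band == b
  rows <- lapply(names(strata), function(nm) {
    in_s <- strata[[nm]]
    n11 <- sum(exposed & flag & in_s)
    n1p <- sum(exposed & in_s)
    data.frame(stratum = nm, n11 = n11, n1plus = n1p,
               rr = reporting_rate(n11, n1p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reporting rate
#'
#' `100 * n11 / n1plus`, rounded half-up to one decimal: the percentage of
#' a group's reported cases that mention the target event. Undefined
#' (`NA`) when the group has no reported cases.
#'
#' @param n11 Event cases within the group.
#' @param n1plus All cases within the group.
#' @return Numeric percentage with one decimal, or `NA` when `n1plus = 0`.
#' @examples
#' reporting_rate(176, 1578)  # 11.2
#' @export
reporting_rate <- function(n11, n1plus) {
  ifelse(n1plus > 0, round_half_up(100 * n11 / n1plus, 1), NA_real_)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (so 11.15 -> 11.2),
#' rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' List event cases exposed to members of two groups
#'
#' Finds flagged cases with at least one exposure (any role) to each of two
#' groups — e.g. patients on both a DPP-4 inhibitor and an ACE inhibitor —
#' and lists their demographics and the member drugs involved, sorted by
#' case id.
#'
#' @param db A `case_db`.
#' @param group_a,group_b Two [drug_group()]s.
#' @param flags Named logical vector from [flag_cases()].
#' @param roles Roles counted; all roles by default, since a combination
#'   case need not have both drugs suspected.
#' @return A data frame with columns `case_id`, `sex`, `age_band`,
#'   `drugs_a`, `drugs_b` (comma-joined member names), `report_year`.
#' @export
find_combination_cases <- function(db, group_a, group_b, flags,
                                   roles = .role_levels) {
  ids_a <- .exposed_ids(db, group_a, roles)
  ids_b <- .exposed_ids(db, group_b, roles)
  flagged <- names(flags)[flags]
  ids <- sort(intersect(intersect(ids_a, ids_b), flagged))
  member_str <- function(id, members) {
    rows <- db$drug$case_id == id & db$drug$drug_name %in% members &
      db$drug$role %in% roles
    paste(sort(unique(db$drug$drug_name[rows])), collapse = ", ")
  }
  demo <- db$demo[match(ids, db$demo$case_id), , drop = FALSE]
  out <- data.frame(
    case_id = ids,
    sex = demo$sex,
    age_band = demo$age_band,
    drugs_a = vapply(ids, member_str, character(1), group_a$members),
    drugs_b = vapply(ids, member_str, character(1), group_b$members),
    report_year = demo$report_year,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
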