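#' Run the full disproportionality analysis
#'
#' Orchestrates read -> exclude -> flag -> count -> score -> classify ->
#' write. The configuration is a named list (or a YAML file path, parsed
#' with the yaml package) with entries:
#' \describe{
#'   \item{demo, drug, reac, hist}{paths to the four tables (hist
#'     optional); alternatively `db`, an in-memory `case_db`.}
#'   \item{column_map}{optional [default_column_map()]-style mapping.}
#'   \item{smq}{path to an SMQ definition file, or an `smq_definition`.}
#'   \item{scope_filter}{`"narrow_and_broad"` (default) or
#'     `"narrow_only"`.}
#'   \item{classes}{named character vector of drug-list paths, or a list
#'     of [drug_group()]s.}
#'   \item{exclusions}{optional [exclusion_rules()]; defaults to all on.}
#'   \item{roles}{drug roles counted as exposure; default `"suspected"`.}
#'   \item{out_dir}{optional output directory for the TSV result tables.}
#' }
#'
#' @param config Named list or YAML path.
#' @return An object of class `pv_analysis`: list with `by_class` and
#'   `by_drug` ([bcpnn()] objects, class row first then members
#'   alphabetical), `strata`, `combinations`, and `log` (retained N++,
#'   exclusion counts, SMQ term count, flagged-case count, cell checksum).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package")
    config <- yaml::read_yaml(config)
  }
  cmap <- config$column_map
  if (is.null(cmap)) cmap <- default_column_map()

  db <- if (!is.null(config$db)) config$db
  else read_report_tables(config$demo, config$drug, config$reac,
                          config$hist, column_map = cmap)
  rules <- if (is.null(config$exclusions)) exclusion_rules()
  else config$exclusions
  exc <- apply_exclusions(db, rules)
  db <- exc$db
  if (n_cases(db) == 0L) stop("no cases retained after exclusions")

  smq <- config$smq
  if (is.character(smq)) smq <- load_smq(smq)
  scope <- if (is.null(config$scope_filter)) "narrow_and_broad"
  else config$scope_filter
  flags <- flag_cases(db, smq, scope)

  groups <- config$classes
  if (is.character(groups))
    groups <- setNames(lapply(seq_along(groups), function(i)
      read_drug_list(groups[i], name = names(groups)[i])), names(groups))
  if (is.null(groups) || !length(groups)) stop("config$classes is required")
  names(groups) <- vapply(groups, function(g) g$name, character(1))
  roles <- if (is.null(config$roles)) "suspected" else config$roles

  score_group <- function(g) {
    present <- g$members %in% db$drug$drug_name
    if (!any(present))
      warning("drug list '", g$name, "' names no drug present in the data")
    class_tab <- count_table(db, g, flags, roles)
    member_tabs <- lapply(sort(g$members), function(m)
      count_table(db, drug_group(m, m), flags, roles))
    list(class_fit = bcpnn(class_tab),
         drug_fit = bcpnn(member_tabs))
  }
  scored <- lapply(groups, score_group)
  by_class <- bcpnn(lapply(groups, function(g)
    count_table(db, g, flags, roles)))
  by_drug <- do.call(rbind, lapply(names(scored), function(nm) {
    df <- as.data.frame(scored[[nm]]$drug_fit)
    cbind(class = nm, df, stringsAsFactors = FALSE)
  }))
  row.names(by_drug) <- NULL
  by_drug <- structure(by_drug, class = c("bcpnn", "data.frame"))

  strata <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g$name,
          stratify_counts(db, g, flags, roles),
          stringsAsFactors = FALSE)))
  row.names(strata) <- NULL

  combinations <- if (length(groups) >= 2L)
    find_combination_cases(db, groups[[1]], groups[[2]], flags)
  else NULL

  log <- list(n_retained = n_cases(db),
              excluded = exc$excluded,
              smq_terms = nrow(smq$terms),
              scope_filter = scope,
              flagged_cases = sum(flags),
              cell_checksum = sum(by_class$n11) + sum(by_class$n1plus) +
                sum(by_drug$n11) + sum(by_drug$n1plus))
  res <- structure(list(by_class = by_class, by_drug = by_drug,
                        strata = strata, combinations = combinations,
                        log = log),
                   class = "pv_analysis")
  if (!is.null(config$out_dir)) write_analysis(res, config$out_dir)
  res
}

#' Write analysis result tables as TSV
#'
#' @param res A `pv_analysis` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p
  }
  paths <- c(wr(res$by_class, "scores_by_class.tsv"),
             wr(res$by_drug, "scores_by_drug.tsv"),
             wr(res$strata, "strata.tsv"))
  if (!is.null(res$combinations))
    paths <- c(paths, wr(res$combinations, "combination_cases.tsv"))
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(paste("retained cases (N++):", res$log$n_retained),
               paste("excluded:", paste(names(res$log$excluded),
                                        res$log$excluded, collapse = ", ")),
               paste("SMQ terms:", res$log$smq_terms,
                     "| scope:", res$log$scope_filter),
               paste("flagged cases (N+1):", res$log$flagged_cases),
               paste("cell checksum:", res$log$cell_checksum)),
             log_path)
  invisible(c(paths, log_path))
}

#' @export
print.pv_analysis <- function(x, ...) {
  cat("Disproportionality analysis:", x$log$n_retained,
      "retained cases,", x$log$flagged_cases, "with the target event\n\n")
  cat("Per-class scores:\n")
  print(x$by_class)
  cat("\nPer-drug signals:\n")
  sig <- x$by_drug[x$by_drug$classification != "none", , drop = FALSE]
  if (nrow(sig)) print.data.frame(format_ic_table(sig), row.names = FALSE)
  else cat("  none\n")
  invisible(x)
}

#' Score a single 2x2 table from its counts
#'
#' Convenience wrapper around [bcpnn()] for one table given as the four
#' counts of the standard signal-detection layout; the exact vehicle for
#' checking published scores.
#'
#' @inheritParams expectation_ic
#' @param label Row label.
#' @return A one-row [bcpnn()] object.
#' @examples
#' score_counts(86, 771, 10802, 534287, label = "enalapril")
#' @export
score_counts <- function(n11, n1plus, nplus1, nplusplus,
                         prior = bcpnn_prior(), label = "table") {
  stopifnot(length(n11) == 1L)
  bcpnn(setNames(n11, label), n1plus = n1plus, nplus1 = nplus1,
        nplusplus = nplusplus, prior = prior)
}
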