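#' Load a Standardized MedDRA Query definition
#'
#' An SMQ is a curated set of MedDRA preferred terms (PTs) representing one
#' medical condition, each term carrying a `narrow` or `broad` scope. The
#' definition file is tab- or comma-separated (sniffed from the header
#' line) with columns `pt_code`, `pt_name`, `smq_id`, `scope`; scope is
#' parsed case-insensitively.
#'
#' @param path Path to the definition file.
#' @return An object of class `smq_definition`: a list with `smq_id`,
#'   `name`, and `terms`, a data frame with columns `pt_code`, `pt_name`,
#'   `scope`.
#' @examples
#' smq <- load_smq(system.file("extdata", "smq_angioedema_synthetic.tsv",
#'                             package = "pvsignal"))
#' smq
#' @export
load_smq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("SMQ definition '", path, "': no terms")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- read.csv(text = paste(lines, collapse = "\n"), sep = sep,
                 stringsAsFactors = FALSE, colClasses = "character")
  need <- c("pt_code", "pt_name", "smq_id", "scope")
  if (!all(need %in% names(df)))
    stop("SMQ definition must have columns ",
         paste(need, collapse = ", "))
  scope <- tolower(trimws(df$scope))
  bad <- which(!scope %in% c("narrow", "broad"))
  if (length(bad))
    stop("SMQ definition '", path, "': unknown scope token '",
         df$scope[bad[1]], "' at line ", bad[1] + 1L)
  df$scope <- scope
  df$pt_code <- trimws(df$pt_code)
  key <- !duplicated(df$pt_code)
  for (code in unique(df$pt_code[duplicated(df$pt_code)])) {
    sc <- unique(df$scope[df$pt_code == code])
    if (length(sc) > 1L)
      stop("SMQ definition '", path, "': PT ", code,
           " listed with conflicting scopes")
  }
  smq_id <- trimws(df$smq_id[1])
  df <- df[key, c("pt_code", "pt_name", "scope"), drop = FALSE]
  rownames(df) <- NULL
  structure(list(smq_id = smq_id, name = paste0("SMQ ", smq_id),
                 terms = df),
            class = "smq_definition")
}

#' Construct an SMQ definition from vectors
#'
#' @param smq_id SMQ code, e.g. `"20000024"`.
#' @param pt_code,scope Parallel vectors of preferred-term codes and their
#'   scopes (`"narrow"` or `"broad"`).
#' @param pt_name Optional term names.
#' @param name Optional SMQ display name.
#' @return An `smq_definition`; see [load_smq()].
#' @export
smq_definition <- function(smq_id, pt_code, scope, pt_name = pt_code,
                           name = paste0("SMQ ", smq_id)) {
  stopifnot(length(pt_code) == length(scope), length(pt_code) >= 1)
  scope <- tolower(scope)
  if (!all(scope %in% c("narrow", "broad")))
    stop("scope must be 'narrow' or 'broad'")
  if (anyDuplicated(pt_code)) stop("duplicate PT codes in SMQ definition")
  structure(list(smq_id = smq_id, name = name,
                 terms = data.frame(pt_code = as.character(pt_code),
                                    pt_name = as.character(pt_name),
                                    scope = scope,
                                    stringsAsFactors = FALSE)),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("SMQ", x$smq_id, "-", x$name, ":",
      sum(x$terms$scope == "narrow"), "narrow +",
      sum(x$terms$scope == "broad"), "broad terms\n")
  invisible(x)
}

#' Flag cases containing an in-scope SMQ term
#'
#' A case is flagged when its event set intersects the selected scope's PT
#' set. A case with several matching PTs is still one flagged case — the
#' case-level deduplication that makes downstream counting case-based.
#'
#' @param db A `case_db`.
#' @param smq An `smq_definition`.
#' @param scope_filter `"narrow_and_broad"` (default, both scopes) or
#'   `"narrow_only"`.
#' @return A named logical vector over all case ids in `db`.
#' @export
flag_cases <- function(db, smq,
                       scope_filter = c("narrow_and_broad", "narrow_only")) {
  scope_filter <- match.arg(scope_filter)
  pts <- if (scope_filter == "narrow_only")
    smq$terms$pt_code[smq$terms$scope == "narrow"]
  else smq$terms$pt_code
  hit_ids <- unique(db$reac$case_id[db$reac$pt %in% pts])
  setNames(db$demo$case_id %in% hit_ids, db$demo$case_id)
}
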