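# Small in-code fixtures shared across test files.

# A hand-built database: 3 cases spread over 7 drug rows and 5 event rows.
tiny_tables <- function() {
  demo <- data.frame(
    case_id = c("C1", "C2", "C3"),
    sex = c("female", "male", "female"),
    age = c("62", "70-79", "38"),
    report_year = c(2015, 2016, 2017),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    case_id = c("C1", "C1", "C1", "C2", "C2", "C3", "C3"),
    drug_name = c("Enalapril", "vildagliptin", "aspirin",
                  "imidapril", "enalapril", "sitagliptin", "aspirin"),
    role = c("suspected", "suspected", "concomitant",
             "suspected", "suspected", "suspected", "unknown"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    case_id = c("C1", "C1", "C2", "C3", "C3"),
    pt = c("PT900001", "PT900004", "PT900001", "PTBG0001", "PTBG0002"),
    stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac)
}

tiny_db <- function() {
  t <- tiny_tables()
  case_db(t$demo, t$drug, t$reac)
}

write_tiny_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  t <- tiny_tables()
  paths <- c(demo = file.path(dir, "DEMO.csv"),
             drug = file.path(dir, "DRUG.csv"),
             reac = file.path(dir, "REAC.csv"))
  write.csv(t$demo, paths["demo"], row.names = FALSE)
  write.csv(t$drug, paths["drug"], row.names = FALSE)
  write.csv(t$reac, paths["reac"], row.names = FALSE)
  paths
}

toy_smq <- function() {
  smq_definition("90000001",
                 pt_code = c("PT900001", "PT900002", "PT900004"),
                 scope = c("narrow", "narrow", "broad"))
}

# Independent brute-force contingency oracle: explicit per-case loop.
brute_force_cells <- function(db, members, flags, roles = "suspected") {
  n11 <- n10 <- n01 <- n00 <- 0L
  for (id in db$demo$case_id) {
    rows <- db$drug[db$drug$case_id == id, , drop = FALSE]
    exposed <- any(rows$drug_name %in% members & rows$role %in% roles)
    flagged <- flags[[id]]
    if (exposed && flagged) n11 <- n11 + 1L
    else if (exposed) n10 <- n10 + 1L
    else if (flagged) n01 <- n01 + 1L
    else n00 <- n00 + 1L
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

# Direct plain-ratio transcription of the IC expectation and variance,
# independent of the package's log-space implementation.
oracle_eic <- function(n11, n1p, np1, npp) {
  g <- (npp + 2) * (npp + 2) / ((n1p + 1) * (np1 + 1))
  log2((n11 + 1) * (npp + 2) * (npp + 2) /
         ((npp + g) * (n1p + 1) * (np1 + 1)))
}
oracle_vic <- function(n11, n1p, np1, npp) {
  g <- (npp + 2) * (npp + 2) / ((n1p + 1) * (np1 + 1))
  (1 / log(2))^2 * ((npp - n11 + g - 1) / ((n11 + 1) * (1 + npp + g)) +
                      (npp - n1p + 1) / ((n1p + 1) * (3 + npp)) +
                      (npp - np1 + 1) / ((np1 + 1) * (3 + npp)))
}

# Reference-scale recovery design: one rare over-reporting drug over a
# dense background of null drugs.
recovery_config <- function(n_cases = 50000, lambda = 4, seed = 1) {
  synthetic_config(
    n_cases,
    data.frame(drug = c("targetdrug", sprintf("backgrounddrug%02d", 1:20)),
               exposure_prob = c(0.003, rep(0.08, 20)),
               lambda = c(lambda, rep(1, 20)),
               class = NA_character_, stringsAsFactors = FALSE),
    baseline_event_prob = 0.02, seed = seed)
}
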