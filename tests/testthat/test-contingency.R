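test_that("a case on two member drugs counts once toward the class margin", {
  db <- tiny_db()  # C2 takes imidapril and enalapril, both suspected
  smq <- toy_smq()
  fl <- flag_cases(db, smq)
  ace <- drug_group("ACE inhibitors", c("enalapril", "imidapril"))
  tab <- count_table(db, ace, fl)
  expect_equal(tab$n1plus, 2L)  # C1 and C2, not 3 exposures
  expect_equal(tab$n11, 2L)     # both are flagged
  # class counts never exceed the sum over members
  members <- lapply(c("enalapril", "imidapril"), function(m)
    count_table(db, drug_group(m, m), fl))
  expect_lte(tab$n11, sum(vapply(members, `[[`, 0, "n11")))
  expect_lte(tab$n1plus, sum(vapply(members, `[[`, 0, "n1plus")))
})

test_that("published class counts obey the dedup relations", {
  ref <- angioedema_reference()
  for (cl in unique(ref$counts$class)) {
    rows <- ref$counts[ref$counts$class == cl, ]
    class_row <- rows[rows$drug == "(class)", ]
    members <- rows[rows$drug != "(class)", ]
    expect_lte(class_row$n11, sum(members$n11))
    expect_lte(class_row$n1plus, sum(members$n1plus))
  }
  # the ACE class: members sum exactly to the class n11 (no shared event
  # case between two members) while the drug margin strictly deduplicates
  ace <- ref$counts[ref$counts$class == "ACE inhibitors", ]
  expect_equal(sum(ace$n11[ace$drug != "(class)"]),
               ace$n11[ace$drug == "(class)"])
  expect_gt(sum(ace$n1plus[ace$drug != "(class)"]),
            ace$n1plus[ace$drug == "(class)"])
})

test_that("cells equal the brute-force per-case enumeration on synthetic data", {
  cfg <- synthetic_config(400, data.frame(
    drug = c("drugx", "drugy", "bg1", "bg2"),
    exposure_prob = c(0.15, 0.10, 0.3, 0.2),
    lambda = c(3, 1, 1, 1),
    class = c("XY", "XY", NA, NA)), seed = 42)
  db <- simulate_reports(cfg)
  fl <- flag_cases(db, smq_for_config(cfg))
  for (g in list(drug_group("drugx", "drugx"),
                 drug_group("XY", c("drugx", "drugy")))) {
    tab <- count_table(db, g, fl)
    bf <- brute_force_cells(db, g$members, fl)
    expect_equal(c(n11 = tab$n11, n10 = tab$n10,
                   n01 = tab$n01, n00 = tab$n00), bf)
    # cells partition the cases
    expect_equal(tab$nplusplus, n_cases(db))
  }
})

test_that("no-exposure groups produce zero margins, not errors", {
  db <- tiny_db()
  fl <- flag_cases(db, toy_smq())
  tab <- count_table(db, drug_group("ghost", "notadrug"), fl)
  expect_equal(tab$n11, 0L)
  expect_equal(tab$n1plus, 0L)
  expect_equal(tab$n01, sum(fl))
  expect_error(drug_group("empty", character()), "no members")
})

test_that("strata counts partition the totals along each axis", {
  cfg <- synthetic_config(600, data.frame(
    drug = c("drugx", "bg1"), exposure_prob = c(0.2, 0.4),
    lambda = c(2, 1), class = NA), seed = 11)
  db <- simulate_reports(cfg)
  fl <- flag_cases(db, smq_for_config(cfg))
  g <- drug_group("drugx", "drugx")
  st <- stratify_counts(db, g, fl)
  total <- st[st$stratum == "Total", ]
  sex_rows <- st[st$stratum %in% c("Female", "Male"), ]
  age_rows <- st[!st$stratum %in% c("Total", "Female", "Male"), ]
  expect_equal(sum(sex_rows$n11), total$n11)
  expect_equal(sum(sex_rows$n1plus), total$n1plus)
  expect_equal(sum(age_rows$n11), total$n11)
  expect_equal(sum(age_rows$n1plus), total$n1plus)
  # per-stratum counts equal the brute-force restriction
  male_ids <- db$demo$case_id[db$demo$sex == "male"]
  db_male <- db
  db_male$demo <- db$demo[db$demo$case_id %in% male_ids, , drop = FALSE]
  db_male$drug <- db$drug[db$drug$case_id %in% male_ids, , drop = FALSE]
  bf <- brute_force_cells(db_male, g$members, fl)
  expect_equal(st$n11[st$stratum == "Male"], unname(bf["n11"]))
  expect_equal(st$n1plus[st$stratum == "Male"],
               unname(bf["n11"] + bf["n10"]))
})

test_that("an all-male database has an all-zero Female row", {
  t <- tiny_tables()
  t$demo$sex <- "male"
  db <- case_db(t$demo, t$drug, t$reac)
  st <- stratify_counts(db, drug_group("enalapril", "enalapril"),
                        flag_cases(db, toy_smq()))
  expect_equal(st$n1plus[st$stratum == "Female"], 0L)
  expect_equal(st$n11[st$stratum == "Female"], 0L)
})

test_that("reporting rates round half-up to one decimal", {
  expect_equal(reporting_rate(176, 1578), 11.2)  # 11.153... -> 11.2
  expect_equal(reporting_rate(101, 6898), 1.5)   # 1.464...  -> 1.5
  expect_equal(reporting_rate(0, 10), 0.0)
  expect_true(is.na(reporting_rate(0, 0)))
  # the half-up convention itself
  expect_equal(round_half_up(11.15, 1), 11.2)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("combination-case listing mirrors the two-class intersection", {
  t <- tiny_tables()  # C1: enalapril + vildagliptin, flagged
  db <- case_db(t$demo, t$drug, t$reac)
  fl <- flag_cases(db, toy_smq())
  ace <- drug_group("ACE", c("enalapril", "imidapril"))
  dpp4 <- drug_group("DPP-4", c("vildagliptin", "sitagliptin"))
  combo <- find_combination_cases(db, ace, dpp4, fl)
  expect_equal(nrow(combo), 1L)
  expect_equal(combo$case_id, "C1")
  expect_equal(combo$drugs_a, "enalapril")
  expect_equal(combo$drugs_b, "vildagliptin")
  expect_equal(combo$report_year, 2015L)
  # no overlap -> empty
  lone <- drug_group("lone", "aspirin")
  none <- find_combination_cases(db, drug_group("x", "imidapril"),
                                 lone, fl)
  expect_equal(nrow(none), 0L)
  # brute-force set intersection on synthetic data
  cfg <- synthetic_config(500, data.frame(
    drug = c("a1", "b1", "bg"), exposure_prob = c(0.3, 0.3, 0.5),
    lambda = c(2, 2, 1), class = NA), seed = 5)
  sdb <- simulate_reports(cfg)
  sfl <- flag_cases(sdb, smq_for_config(cfg))
  got <- find_combination_cases(sdb, drug_group("A", "a1"),
                                drug_group("B", "b1"), sfl)
  want <- sort(intersect(
    intersect(unique(sdb$drug$case_id[sdb$drug$drug_name == "a1"]),
              unique(sdb$drug$case_id[sdb$drug$drug_name == "b1"])),
    names(sfl)[sfl]))
  expect_equal(got$case_id, want)
})
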