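test_that("flat CSV rows sharing a report id collapse into one report", {
  csv <- file.path(tempdir(), "flat1.csv")
  writeLines(c(
    "report_id,case_version,receipt_date,sex,age_years,age_unit,region,serious,drug_name,drug_role,therapy_start,pt,onset_date,outcome",
    "R1,1,2024-05-01,female,34,yr,americas,false,drugA,suspect,2024-04-01,Headache,2024-04-03,recovered",
    "R1,1,2024-05-01,female,34,yr,americas,false,drugB,concomitant,2024-04-01,Headache,2024-04-03,recovered",
    "R1,1,2024-05-01,female,34,yr,americas,false,drugA,suspect,2024-04-01,Headache,2024-04-03,recovered"
  ), csv)
  store <- read_reports(csv, "flat_csv")
  expect_equal(nrow(store$reports), 1L)
  expect_equal(nrow(store$drugs), 2L)
  expect_equal(nrow(store$reactions), 1L)
  expect_equal(store$reports$sex, "female")
  expect_equal(store$reports$age_years, 34)
})

test_that("header-only file yields an empty store; missing columns are named", {
  csv <- file.path(tempdir(), "flat_empty.csv")
  writeLines(paste(c("report_id", "case_version", "receipt_date", "sex",
                     "age_years", "age_unit", "region", "serious", "drug_name",
                     "drug_role", "therapy_start", "pt", "onset_date",
                     "outcome"), collapse = ","), csv)
  expect_equal(nrow(read_reports(csv, "flat_csv")$reports), 0L)

  bad <- file.path(tempdir(), "flat_bad.csv")
  writeLines(c("report_id,case_version,sex", "R1,1,male"), bad)
  expect_error(read_reports(bad, "flat_csv"), "receipt_date")
})

test_that("missing demographics become explicit unknowns, bad dates warn", {
  csv <- file.path(tempdir(), "flat2.csv")
  writeLines(c(
    "report_id,case_version,receipt_date,sex,age_years,age_unit,region,serious,drug_name,drug_role,therapy_start,pt,onset_date,outcome",
    "R1,1,2024-05-01,,,,,,drugA,suspect,not-a-date,Rash,,",
    "R2,1,2024-05-01,male,480,mon,europe,true,drugA,suspect,,Rash,2024-05-02,fatal"
  ), csv)
  expect_warning(store <- read_reports(csv, "flat_csv"), "therapy_start")
  expect_equal(store$reports$sex, c("unknown", "male"))
  expect_true(is.na(store$reports$age_years[1]))
  expect_equal(store$reports$age_years[2], 40) # 480 months
  expect_equal(store$reports$region, c("unknown", "europe"))
  expect_true(is.na(store$drugs$therapy_start[store$drugs$report_id == "R1"]))
  expect_equal(nrow(store$reports), 2L)
})

test_that("write_reports / read_reports round-trips a synthetic store", {
  sim <- generate_reports(small_config(seed = 11, n_target_reports = 100,
                                       n_background_records = 2000,
                                       duplicate_fraction = 0.05))
  csv <- file.path(tempdir(), "roundtrip.csv")
  write_reports(sim$store, csv)
  back <- read_reports(csv, "flat_csv")
  canon <- function(s) {
    list(
      reports = s$reports |> arrange(report_id, case_version),
      drugs = s$drugs |> select(report_id, case_version, drug_name, role,
                                therapy_start, drug_norm) |>
        arrange(report_id, drug_name, role),
      reactions = s$reactions |> arrange(report_id, pt, onset_date)
    )
  }
  expect_equal(canon(back), canon(sim$store), ignore_attr = TRUE)
})

test_that("faers_ascii dialect joins DEMO/DRUG/REAC/THER and maps codes", {
  dir <- file.path(tempdir(), "faers_fixture")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$occr_country$extra",
               "1001$C1$2$20240315$F$420$mon$US$x",
               "1002$C2$1$202403$M$44$yr$JP$y",
               "1003$C3$1$2024$$$$$z"),
             file.path(dir, "demo_q1.txt"))
  writeLines(c("primaryid$drug_seq$drugname$role_cod",
               "1001$1$BRIUMVI.$PS", "1001$2$Clemastine$C",
               "1002$1$briumvi$SS", "1003$1$otherdrug$I"),
             file.path(dir, "drug_q1.txt"))
  writeLines(c("primaryid$pt", "1001$Infusion related reaction",
               "1001$Headache", "1002$Rash", "1003$Rash"),
             file.path(dir, "reac_q1.txt"))
  writeLines(c("primaryid$dsg_drug_seq$start_dt", "1001$1$20240301"),
             file.path(dir, "ther_q1.txt"))
  store <- read_reports(dir, "faers_ascii")
  expect_equal(nrow(store$reports), 3L)
  r1 <- store$reports[store$reports$report_id == "C1", ]
  expect_equal(r1$sex, "female")
  expect_equal(r1$age_years, 35) # 420 months
  expect_equal(r1$case_version, 2L)
  expect_equal(r1$region, "americas")
  expect_equal(r1$receipt_date, as.Date("2024-03-15"))
  # partial dates resolve to the first day of the period
  expect_equal(store$reports$receipt_date[store$reports$report_id == "C2"],
               as.Date("2024-03-01"))
  expect_equal(store$reports$receipt_date[store$reports$report_id == "C3"],
               as.Date("2024-01-01"))
  expect_setequal(
    store$drugs$role[store$drugs$report_id == "C1"],
    c("suspect", "concomitant"))
  expect_equal(store$drugs$therapy_start[store$drugs$report_id == "C1" &
                                           store$drugs$role == "suspect"],
               as.Date("2024-03-01"))
  # normalized matching finds the brand-name spellings
  sel <- select_drug_reports(store, "briumvi")
  expect_setequal(sel$reports$report_id, c("C1", "C2"))
})

test_that("deduplicate applies the version rule, content rule, and is idempotent", {
  store <- mk_store(
    rpt("R1", pts = "ptA", version = 1, receipt = "2024-01-01"),
    rpt("R1", pts = c("ptA", "ptB"), version = 2, receipt = "2024-02-01"),
    rpt("R2", pts = "ptC", sex = "female", age = 50, receipt = "2024-03-01"),
    rpt("R3", pts = "ptC", sex = "female", age = 50, receipt = "2024-03-01"),
    rpt("R4", pts = "ptC", sex = "male", age = 50, receipt = "2024-03-01")
  )
  dd <- deduplicate(store)
  # R1 keeps only version 2; R2/R3 share the content 5-tuple -> R2 survives
  expect_setequal(dd$reports$report_id, c("R1", "R2", "R4"))
  expect_equal(dd$reports$case_version[dd$reports$report_id == "R1"], 2L)
  expect_setequal(dd$reactions$pt[dd$reactions$report_id == "R1"],
                  c("ptA", "ptB"))
  # idempotence and monotonicity
  dd2 <- deduplicate(dd)
  expect_equal(dd2$reports, dd$reports)
  expect_lte(nrow(dd$reports), nrow(store$reports))
  # no-duplicate store is unchanged
  clean <- mk_store(rpt("A", "ptA"), rpt("B", "ptB", sex = "male"))
  expect_setequal(deduplicate(clean)$reports$report_id, c("A", "B"))
})

test_that("select_drug_reports filters by role and is monotone in the role set", {
  store <- mk_store(
    rpt("R1", "ptA", drugs = "targetdrug", roles = "suspect"),
    rpt("R2", "ptA", drugs = "targetdrug", roles = "concomitant"),
    rpt("R3", "ptA", drugs = c("targetdrug", "other"),
        roles = c("suspect", "concomitant")),
    rpt("R4", "ptA", drugs = "Target-Drug ", roles = "suspect"),
    rpt("R5", "ptA", drugs = "unrelated")
  )
  suspect_only <- select_drug_reports(store, "TARGETDRUG", roles = "suspect")
  expect_setequal(suspect_only$reports$report_id, c("R1", "R3"))
  both <- select_drug_reports(store, "targetdrug",
                              roles = c("suspect", "concomitant"))
  expect_true(all(suspect_only$reports$report_id %in% both$reports$report_id))
  # synonym table maps brand to generic; normalization strips punctuation
  syn <- tibble(alias = "Target-Drug", canonical = "targetdrug")
  with_syn <- select_drug_reports(store, "targetdrug", synonyms = syn)
  expect_true("R4" %in% with_syn$reports$report_id)
  expect_equal(nrow(select_drug_reports(store, "absentdrug")$reports), 0L)
})

test_that("synthetic store honors the generator's target-report manifest", {
  sim <- generate_reports(small_config(seed = 3, n_target_reports = 123))
  sel <- select_drug_reports(sim$store, "ublituximab")
  expect_equal(nrow(sel$reports), 123L)
  expect_equal(sim$manifest$n_target_reports, 123L)
})
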