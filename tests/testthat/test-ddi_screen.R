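test_that("partners rank by co-report count with alphabetical ties", {
  specs <- c(
    lapply(1:7, function(i) rpt(sprintf("P%02d", i), "ptA",
                                drugs = c("basedrug", "partnerP"),
                                roles = c("suspect", "concomitant"))),
    lapply(8:10, function(i) rpt(sprintf("Q%02d", i), "ptA",
                                 drugs = c("basedrug", "partnerQ"),
                                 roles = c("suspect", "concomitant"))),
    lapply(11:13, function(i) rpt(sprintf("Z%02d", i), "ptA",
                                  drugs = c("basedrug", "partnerA"),
                                  roles = c("suspect", "concomitant"))),
    list(rpt("X01", "ptB", drugs = "loner"))
  )
  store <- do.call(mk_store, specs)
  tp <- top_partners(store, "basedrug", k = 3)
  expect_equal(tp$partner, c("partnerp", "partnera", "partnerq"))
  expect_equal(tp$n_reports, c(7, 3, 3))
  expect_equal(nrow(top_partners(store, "absent", k = 3)), 0L)
})

test_that("top_partners matches brute-force pair counting on a random fixture", {
  set.seed(53)
  all_drugs <- c("basedrug", paste0("pd", 1:6))
  specs <- lapply(1:100, function(i) {
    drugs <- sample(all_drugs, sample(1:3, 1))
    rpt(sprintf("R%03d", i), "ptA", drugs = drugs,
        roles = rep("suspect", length(drugs)))
  })
  store <- do.call(mk_store, specs)
  tp <- top_partners(store, "basedrug", k = 10)
  # oracle: count reports containing both drugs by explicit double loop
  for (p in paste0("pd", 1:6)) {
    n <- 0
    for (i in 1:100) {
      id <- sprintf("R%03d", i)
      dn <- store$drugs$drug_name[store$drugs$report_id == id]
      if ("basedrug" %in% dn && p %in% dn) n <- n + 1
    }
    got <- tp$n_reports[tp$partner == p]
    expect_equal(if (length(got)) got else 0, n, info = p)
  }
})

test_that("combination exposure reports are a subset of base-drug reports", {
  sim <- generate_reports(small_config(seed = 61, n_target_reports = 300))
  store <- sim$store
  base_ids <- select_drug_reports(store, "ublituximab")$reports$report_id
  partner_ids <- select_drug_reports(store, "umbralisib")$reports$report_id
  combo_ids <- intersect(base_ids, partner_ids)
  expect_gt(length(combo_ids), 0)
  pt1 <- store$reactions$pt[store$reactions$report_id %in% combo_ids][1]
  cs <- build_table(store, combination_exposure("ublituximab", "umbralisib"),
                    pt1)
  combo_records <- nrow(dplyr::distinct(
    store$reactions[store$reactions$report_id %in% combo_ids, ],
    report_id, pt))
  expect_equal(cs$a + cs$b, combo_records)
})

test_that("a combination-restricted signal is combination-specific; a base-wide one is not", {
  # Constructed world with exact counts. evtx is enriched only among the 100
  # combination reports (+14 on a base-wide expectation of ~50): far outside
  # the tight combination-screen null band, inside the base screen's. evty is
  # enriched across all base reports, so both screens flag it.
  filler <- function(i) sprintf("f%02d", (i %% 20) + 1)
  ids_combo <- sprintf("CB%04d", 1:100)
  ids_base <- sprintf("BA%04d", 1:1900)
  ids <- c(ids_combo, ids_base, "BG1", "BG2", "BG3")
  reports <- tibble::tibble(
    report_id = ids, case_version = 1L,
    receipt_date = as.Date("2024-01-01"), sex = "unknown",
    age_years = NA_real_, region = "unknown", serious = FALSE,
    weight = c(rep(1, 2000), 750, 750, 28500))
  drugs <- tibble::tibble(
    report_id = c(ids_combo, ids_combo, ids_base, "BG1", "BG2", "BG3"),
    case_version = 1L,
    drug_name = c(rep("ublituximab", 100), rep("comedx", 100),
                  rep("ublituximab", 1900), rep("otherdrug", 3)),
    role = c(rep("suspect", 100), rep("concomitant", 100),
             rep("suspect", 1900), rep("suspect", 3)),
    therapy_start = as.Date(NA))
  first_pt <- c(rep("evtx", 14), rep("evty", 15), filler(30:100), # combo
                rep("evtx", 48), rep("evty", 300), filler(349:1900), # base
                "evtx", "evty", "f02")
  second_pt <- c(filler(1:2000 + 1), "f01", "f01", "f03") # offset: never collides
  reactions <- tibble::tibble(
    report_id = rep(ids, 2), case_version = 1L,
    pt = c(first_pt, second_pt),
    onset_date = as.Date(NA), outcome = "unknown")
  store <- report_store(reports, drugs, reactions)
  hier <- as_hierarchy(tibble::tibble(
    pt = c("evtx", "evty", sprintf("f%02d", 1:20)), soc = "soc1"))
  res <- combination_screen(store,
                            combination_exposure("ublituximab", "comedx"),
                            hier)
  combo_only <- res$rows[res$rows$pt == "evtx", ]
  expect_true(combo_only$positive)
  expect_true(combo_only$combination_specific)
  expect_false(combo_only$base_drug_positive)
  base_wide <- res$rows[res$rows$pt == "evty", ]
  expect_true(base_wide$positive)
  expect_true(base_wide$base_drug_positive)
  expect_false(base_wide$combination_specific)
  # a PT never reported for the combination is absent from the output
  expect_true(all(res$rows$a >= 3))
})

test_that("base and partner must differ after normalization", {
  expect_error(combination_exposure("DRUGA ", "drugA"), "differ")
  syn <- tibble::tibble(alias = "brandx", canonical = "genericx")
  expect_error(combination_exposure("BrandX", "genericx", synonyms = syn),
               "differ")
})
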