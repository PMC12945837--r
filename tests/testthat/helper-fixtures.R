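# Fixture builders and independent brute-force oracles shared across tests.

library(tibble)
library(dplyr)

# One report spec for mk_store(); drugs and roles are parallel vectors, as are
# pts and onsets.
rpt <- function(id, pts, drugs = "targetdrug", roles = "suspect",
                version = 1L, sex = "unknown", age = NA_real_,
                receipt = "2024-01-01", start = NA, onsets = NA,
                region = "americas", serious = FALSE, outcome = "unknown",
                weight = 1) {
  list(id = id, pts = pts, drugs = drugs,
       roles = rep_len(roles, length(drugs)), version = as.integer(version),
       sex = sex, age = age, receipt = as.Date(receipt),
       start = as.Date(start), onsets = rep_len(as.Date(onsets), length(pts)),
       region = region, serious = serious, outcome = outcome, weight = weight)
}

mk_store <- function(..., provenance = "fixture") {
  rs <- list(...)
  reports <- tibble(
    report_id = vapply(rs, function(r) r$id, character(1)),
    case_version = vapply(rs, function(r) r$version, integer(1)),
    receipt_date = as.Date(vapply(rs, function(r) as.character(r$receipt),
                                  character(1))),
    sex = vapply(rs, function(r) r$sex, character(1)),
    age_years = vapply(rs, function(r) as.numeric(r$age), numeric(1)),
    region = vapply(rs, function(r) r$region, character(1)),
    serious = vapply(rs, function(r) r$serious, logical(1)),
    weight = vapply(rs, function(r) as.numeric(r$weight), numeric(1))
  )
  drugs <- bind_rows(lapply(rs, function(r) {
    tibble(report_id = r$id, case_version = r$version, drug_name = r$drugs,
           role = r$roles, therapy_start = rep_len(r$start, length(r$drugs)))
  }))
  reactions <- bind_rows(lapply(rs, function(r) {
    tibble(report_id = r$id, case_version = r$version, pt = r$pts,
           onset_date = r$onsets, outcome = r$outcome)
  }))
  report_store(reports, drugs, reactions, provenance = provenance)
}

# Quadratic, first-principles 2x2 recount, independent of the package's
# counting machinery: loop over reports, collect distinct PTs, tally cells.
brute_table <- function(store, drug, event, unit = "record",
                        sex_filter = "any", age_filter = "any") {
  drug <- pvscreen::normalize_drug_name(drug)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(store$reports))) {
    row <- store$reports[i, ]
    if (sex_filter != "any" && row$sex != sex_filter) next
    if (age_filter != "any") {
      bin <- pvscreen::age_bin(row$age_years)
      if (is.na(bin) || bin != age_filter) next
    }
    dn <- pvscreen::normalize_drug_name(
      store$drugs$drug_name[store$drugs$report_id == row$report_id])
    exposed <- drug %in% dn
    pts <- unique(store$reactions$pt[store$reactions$report_id == row$report_id])
    w <- row$weight
    if (unit == "record") {
      for (p in pts) {
        if (exposed && p == event) a <- a + w
        else if (exposed) b <- b + w
        else if (p == event) c_ <- c_ + w
        else d <- d + w
      }
    } else {
      if (exposed && event %in% pts) a <- a + w
      if (exposed && length(setdiff(pts, event))) b <- b + w
      if (!exposed && event %in% pts) c_ <- c_ + w
      if (!exposed && length(setdiff(pts, event))) d <- d + w
    }
  }
  c(a = a, b = b, c = c_, d = d)
}

# A random small store over a PT alphabet: ~half the reports carry the target
# drug; demographics drawn at random. Used by the recount oracle tests.
random_store <- function(n = 50, n_pt = 8, seed = 1) {
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    npt <- sample(1:3, 1)
    rpt(
      id = sprintf("R%03d", i),
      pts = sample(paste0("pt", seq_len(n_pt)), npt),
      drugs = if (runif(1) < 0.5) "targetdrug" else
        sample(c("otherdrug1", "otherdrug2"), 1),
      sex = sample(c("male", "female", "unknown"), 1),
      age = if (runif(1) < 0.3) NA_real_ else runif(1, 5, 90),
      receipt = as.character(as.Date("2024-01-01") + sample(0:100, 1))
    )
  })
  do.call(mk_store, specs)
}

hier_for <- function(store, extra = character(0)) {
  pts <- sort(unique(c(store$reactions$pt, extra)))
  pvscreen::as_hierarchy(tibble(pt = pts,
                                soc = paste0("soc_", (seq_along(pts) - 1) %% 4)))
}

# Uniform null catalog for calibration-style worlds
uniform_catalog <- function(n_pt = 50) {
  tibble(pt = sprintf("npt%03d", seq_len(n_pt)),
         soc = paste0("soc_", (seq_len(n_pt) - 1) %% 10),
         background_probability = rep(1 / n_pt, n_pt))
}

# Small, fast synthetic world for tests that only need structure, not scale
small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_background_records = 2e4, n_target_reports = 400,
    pt_catalog = uniform_catalog(50), injected_signals = tibble(
      pt = character(), rr = numeric(), sex = character(),
      age = character(), partner_drug = character()),
    duplicate_fraction = 0
  )
  # no modifyList: it would recurse into tibble components
  defaults[names(args)] <- args
  do.call(pvscreen::synthetic_config, defaults)
}
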