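#' Default PT catalog for the synthetic reporting database
#'
#' A catalog of preferred terms with primary SOC assignments and background
#' reporting probabilities. The leading entries are the common PTs of the
#' published monoclonal-antibody signal tables (infusion-related reaction,
#' infection PTs, neurological PTs, ...); the remainder are generic filler
#' terms spread over 20 SOCs. The named signal PTs carry small background
#' probabilities (order 1e-4 to 1e-2, matching the background reporting
#' shares their published contingency margins imply — drug-specific events
#' are rare among all-other-drug reports); the filler terms share the
#' remaining mass on a Zipf profile (probability proportional to 1/rank),
#' mimicking the heavy-tailed PT frequency distribution of spontaneous-report
#' databases. Keeping signal PTs rare in the background is what lets a large
#' injected relative reporting ratio be realized without the renormalized
#' draw probabilities saturating.
#'
#' @param n_pt total number of PTs (>= 24).
#' @return tibble with `pt`, `soc`, `background_probability`.
#' @export
default_pt_catalog <- function(n_pt = 120) {
  stopifnot(n_pt >= 24)
  named <- tibble(
    pt = c("infusion related reaction", "infusion site discomfort",
           "covid-19 pneumonia", "infusion site swelling",
           "infusion site erythema", "infusion site pain",
           "maternal exposure during breast feeding", "brain fog",
           "intentional dose omission", "respiratory tract infection",
           "oral herpes", "multiple sclerosis",
           "inappropriate schedule of product administration",
           "acute respiratory failure", "multiple sclerosis relapse",
           "covid-19", "urinary tract infection", "illness", "hypoaesthesia",
           "muscular weakness", "headache", "fatigue", "balance disorder",
           "completed suicide"),
    soc = c("injury, poisoning and procedural complications",
            "general disorders and administration site conditions",
            "infections and infestations",
            "general disorders and administration site conditions",
            "general disorders and administration site conditions",
            "general disorders and administration site conditions",
            "injury, poisoning and procedural complications",
            "nervous system disorders",
            "injury, poisoning and procedural complications",
            "infections and infestations",
            "infections and infestations",
            "nervous system disorders",
            "injury, poisoning and procedural complications",
            "respiratory, thoracic and mediastinal disorders",
            "nervous system disorders",
            "infections and infestations",
            "infections and infestations",
            "general disorders and administration site conditions",
            "nervous system disorders",
            "musculoskeletal and connective tissue disorders",
            "nervous system disorders",
            "general disorders and administration site conditions",
            "nervous system disorders",
            "psychiatric disorders")
  )
  named$background_probability <- c(
    0.0010, 0.0002, 0.0005, 0.0002, 0.0003, 0.0005, 0.0002, 0.0003, 0.0008,
    0.0010, 0.0008, 0.0020, 0.0090, 0.0007, 0.0030, 0.0070, 0.0065, 0.0030,
    0.0060, 0.0045, 0.0200, 0.0300, 0.0035, 0.0010
  )
  filler_socs <- c(
    "blood and lymphatic system disorders", "cardiac disorders",
    "eye disorders", "gastrointestinal disorders", "hepatobiliary disorders",
    "immune system disorders", "metabolism and nutrition disorders",
    "neoplasms benign, malignant and unspecified", "psychiatric disorders",
    "renal and urinary disorders", "reproductive system and breast disorders",
    "skin and subcutaneous tissue disorders", "vascular disorders",
    "investigations", "social circumstances", "ear and labyrinth disorders",
    "endocrine disorders", "infections and infestations",
    "nervous system disorders", "gastrointestinal disorders"
  )
  n_fill <- n_pt - nrow(named)
  p_fill <- 1 / seq_len(n_fill)
  filler <- tibble(
    pt = sprintf("pt_%03d", seq_len(n_fill)),
    soc = rep_len(filler_socs, n_fill),
    background_probability = p_fill / sum(p_fill) *
      (1 - sum(named$background_probability))
  )
  bind_rows(named, filler)
}

#' Configure the synthetic spontaneous-report generator
#'
#' Defaults encode the reporting-database conditions of the motivating
#' analysis: a target drug with 1,235 reports against a much larger background
#' (scaled to 2e5 records so desk-scale runs stay fast), reports carrying
#' `1 + Poisson(0.8)` reactions, a female-skewed sex mix (female:male =
#' 3.02:1 among known), 49.7% missing age, 42.11% missing onset timing, 18.3%
#' serious reports, a 5-day median onset delay, and exact-duplicate reports.
#' Default injected signals emulate the headline findings: a very strong
#' infusion-related-reaction signal, infusion-site and infection signals, a
#' weak fatigue signal, a female-restricted headache signal, and a
#' combination-restricted completed-suicide signal with clemastine.
#'
#' @param seed integer RNG seed (reproducibility: same config, same output).
#' @param n_background_records approximate number of background (drug, PT)
#'   event records.
#' @param n_target_reports number of target-drug reports before duplication.
#' @param reactions_mean_extra mean of the Poisson count of extra reactions
#'   per report (reactions per report = 1 + Poisson).
#' @param pt_catalog tibble `pt`, `soc`, `background_probability`
#'   (probabilities must be positive and sum to <= 1; renormalized at draw).
#' @param injected_signals tibble with `pt`, `rr` (relative reporting ratio
#'   > 0) and optional restriction columns `sex`, `age`, `partner_drug`
#'   (`NA` = unrestricted).
#' @param target_drug,partner_drugs target drug name and tibble
#'   `drug`, `prob` of co-administration probabilities.
#' @param sex_mix female fraction among reports with known sex.
#' @param missing_sex_fraction,missing_age_fraction,missing_tto_fraction
#'   missingness fractions.
#' @param age_mean,age_sd normal age model (years), truncated to [1, 95].
#' @param region_mix named probabilities over the region levels.
#' @param serious_fraction fraction of serious reports.
#' @param onset_median_days median of the geometric onset-delay model (days).
#' @param duplicate_fraction fraction of target reports receiving an
#'   exact-content duplicate under a new report id.
#' @param n_background_drugs size of the background drug pool.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_background_records = 2e5,
    n_target_reports = 1235,
    reactions_mean_extra = 0.8,
    pt_catalog = default_pt_catalog(),
    injected_signals = default_injected_signals(),
    target_drug = "ublituximab",
    partner_drugs = default_partner_drugs(),
    sex_mix = 0.751,
    missing_sex_fraction = 0.05,
    missing_age_fraction = 0.497,
    age_mean = 46, age_sd = 15,
    region_mix = c(americas = 0.85, europe = 0.09, asia = 0.005,
                   oceania = 0.01, africa = 0.005, unknown = 0.04),
    serious_fraction = 0.183,
    onset_median_days = 5,
    missing_tto_fraction = 0.4211,
    duplicate_fraction = 0.02,
    n_background_drugs = 400) {
  pt_catalog <- as_tibble(pt_catalog)
  stopifnot(
    all(c("pt", "soc", "background_probability") %in% names(pt_catalog)),
    nrow(pt_catalog) > 0,
    all(pt_catalog$background_probability > 0),
    sum(pt_catalog$background_probability) <= 1 + 1e-9
  )
  injected_signals <- as_tibble(injected_signals)
  if (nrow(injected_signals)) {
    stopifnot(all(c("pt", "rr") %in% names(injected_signals)),
              all(injected_signals$rr > 0),
              all(injected_signals$pt %in% pt_catalog$pt))
  }
  for (col in c("sex", "age", "partner_drug")) {
    if (!col %in% names(injected_signals)) injected_signals[[col]] <- NA_character_
  }
  probs <- c(sex_mix, missing_sex_fraction, missing_age_fraction,
             missing_tto_fraction, serious_fraction, duplicate_fraction,
             region_mix)
  stopifnot(all(probs >= 0 & probs <= 1), onset_median_days > 0,
            n_target_reports >= 1)
  structure(
    list(seed = as.integer(seed), n_background_records = n_background_records,
         n_target_reports = n_target_reports,
         reactions_mean_extra = reactions_mean_extra, pt_catalog = pt_catalog,
         injected_signals = injected_signals, target_drug = target_drug,
         partner_drugs = as_tibble(partner_drugs), sex_mix = sex_mix,
         missing_sex_fraction = missing_sex_fraction,
         missing_age_fraction = missing_age_fraction,
         age_mean = age_mean, age_sd = age_sd, region_mix = region_mix,
         serious_fraction = serious_fraction,
         onset_median_days = onset_median_days,
         missing_tto_fraction = missing_tto_fraction,
         duplicate_fraction = duplicate_fraction,
         n_background_drugs = n_background_drugs),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_injected_signals <- function() {
  tibble(
    pt = c("infusion related reaction", "infusion site discomfort",
           "covid-19 pneumonia", "urinary tract infection", "fatigue",
           "headache", "completed suicide"),
    rr = c(260, 88, 18, 4.7, 2.6, 3, 20),
    sex = c(NA, NA, NA, NA, NA, "female", NA),
    age = NA_character_,
    partner_drug = c(NA, NA, NA, NA, NA, NA, "clemastine")
  )
}

#' @rdname synthetic_config
#' @export
default_partner_drugs <- function() {
  tibble(
    drug = c("umbralisib", "clemastine", "armodafinil", "atorvastatin",
             "ocrelizumab", "paracetamol", "prednisone", "sertraline"),
    prob = c(0.12, 0.08, 0.06, 0.05, 0.04, 0.04, 0.03, 0.02)
  )
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic spontaneous-report database with known ground truth
#'
#' Target-drug reports draw each reaction PT with probability proportional to
#' `background_probability * RR(pt)` (renormalized), where the relative
#' reporting ratio applies only inside a signal's sex/age/partner restriction;
#' background reports draw from the background probabilities. Demographics,
#' onset delays, missingness and exact duplicates follow the configuration.
#' The returned manifest records, per PT, the true RR and the realized
#' contingency cells recovered from the deduplicated store.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `store` (a [report_store()], duplicates included) and
#'   `manifest` (ground truth: `pt_truth` tibble with `rr`, `a`, `b`, `c`,
#'   `d`, `expected_a`; duplicate pairs; realized report counts).
#' @export
generate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed %||% config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  cat_pt <- cfg$pt_catalog$pt
  bg_p <- cfg$pt_catalog$background_probability / sum(cfg$pt_catalog$background_probability)
  n_bg <- max(1L, ceiling(cfg$n_background_records / (1 + cfg$reactions_mean_extra)))
  n_tg <- cfg$n_target_reports
  n_all <- n_bg + n_tg
  ids <- c(sprintf("BG%07d", seq_len(n_bg)), sprintf("TG%06d", seq_len(n_tg)))
  is_target <- c(rep(FALSE, n_bg), rep(TRUE, n_tg))

  # demographics for every report
  sex <- ifelse(runif(n_all) < cfg$missing_sex_fraction, "unknown",
                ifelse(runif(n_all) < cfg$sex_mix, "female", "male"))
  age <- pmin(pmax(rnorm(n_all, cfg$age_mean, cfg$age_sd), 1), 95)
  age[runif(n_all) < cfg$missing_age_fraction] <- NA_real_
  region <- sample(names(cfg$region_mix), n_all, replace = TRUE,
                   prob = cfg$region_mix)
  serious <- runif(n_all) < cfg$serious_fraction
  receipt <- as.Date("2022-12-01") + sample.int(759, n_all, replace = TRUE) - 1L
  therapy_start <- receipt - rpois(n_all, 60)

  reports <- tibble(report_id = ids, case_version = 1L, receipt_date = receipt,
                    sex = sex, age_years = age, region = region,
                    serious = serious, weight = 1)

  # drug entries: one background drug per background report; target drug
  # (suspect) plus Bernoulli partner drugs (concomitant) per target report
  bg_pool <- c(sprintf("backgrounddrug%03d", seq_len(cfg$n_background_drugs)),
               cfg$partner_drugs$drug)
  drugs_bg <- tibble(report_id = ids[!is_target], case_version = 1L,
                     drug_name = sample(bg_pool, n_bg, replace = TRUE),
                     role = "suspect",
                     therapy_start = therapy_start[!is_target])
  drugs_tg <- tibble(report_id = ids[is_target], case_version = 1L,
                     drug_name = cfg$target_drug, role = "suspect",
                     therapy_start = therapy_start[is_target])
  partner_entries <- lapply(seq_len(nrow(cfg$partner_drugs)), function(i) {
    take <- runif(n_tg) < cfg$partner_drugs$prob[i]
    tibble(report_id = ids[is_target][take], case_version = 1L,
           drug_name = cfg$partner_drugs$drug[i], role = "concomitant",
           therapy_start = therapy_start[is_target][take])
  })
  drugs <- bind_rows(drugs_bg, drugs_tg, bind_rows(partner_entries))

  # reaction counts and PT draws
  n_reac <- 1L + rpois(n_all, cfg$reactions_mean_extra)
  # background draws: plain background probabilities
  bg_draws <- tibble(
    report_id = rep(ids[!is_target], n_reac[!is_target]),
    pt = sample(cat_pt, sum(n_reac[!is_target]), replace = TRUE, prob = bg_p)
  )
  # target draws: per-report effective probabilities through the injected RRs
  sig <- cfg$injected_signals
  tg_ids <- ids[is_target]
  applies <- matrix(TRUE, nrow = n_tg, ncol = nrow(sig))
  if (nrow(sig)) {
    for (j in seq_len(nrow(sig))) {
      ok <- rep(TRUE, n_tg)
      if (!is.na(sig$sex[j])) ok <- ok & sex[is_target] == sig$sex[j]
      if (!is.na(sig$age[j])) {
        ok <- ok & !is.na(age[is_target]) & age_bin(age[is_target]) == sig$age[j]
      }
      if (!is.na(sig$partner_drug[j])) {
        pid <- drugs$report_id[normalize_drug_name(drugs$drug_name) ==
                                 normalize_drug_name(sig$partner_drug[j])]
        ok <- ok & tg_ids %in% pid
      }
      applies[, j] <- ok
    }
  }
  group_key <- if (nrow(sig)) apply(applies, 1, paste, collapse = "") else rep("", n_tg)
  expected_a <- setNames(numeric(length(cat_pt)), cat_pt)
  tg_draw_list <- list()
  for (key in unique(group_key)) {
    members <- which(group_key == key)
    rr_vec <- rep(1, length(cat_pt))
    if (nrow(sig)) {
      on <- applies[members[1], ]
      idx <- match(sig$pt, cat_pt)
      rr_vec[idx[on]] <- rr_vec[idx[on]] * sig$rr[on]
    }
    p_eff <- bg_p * rr_vec
    p_eff <- p_eff / sum(p_eff)
    counts <- n_reac[is_target][members]
    tg_draw_list[[key]] <- tibble(
      report_id = rep(tg_ids[members], counts),
      pt = sample(cat_pt, sum(counts), replace = TRUE, prob = p_eff)
    )
    expected_a <- expected_a + sum(counts) * p_eff
  }
  tg_draws <- bind_rows(tg_draw_list)

  # collapse duplicate PT draws within a report
  reac_bg <- bg_draws |> distinct(.data$report_id, .data$pt)
  reac_tg <- tg_draws |> distinct(.data$report_id, .data$pt)

  # onset delays: geometric with the configured median, so that
  # P(delay >= median) = 1/2; unknown timing per report
  p_geom <- 1 - 2^(-1 / cfg$onset_median_days)
  delay <- rgeom(nrow(reac_tg), p_geom)
  start_of <- setNames(therapy_start[is_target], tg_ids)
  onset <- start_of[reac_tg$report_id] + delay
  tto_missing <- runif(n_tg) < cfg$missing_tto_fraction
  onset[tto_missing[match(reac_tg$report_id, tg_ids)]] <- as.Date(NA)
  outcomes <- c("recovered", "recovering", "not_recovered", "fatal", "unknown")
  out_p <- c(0.35, 0.15, 0.25, 0.02, 0.23)
  reactions <- bind_rows(
    reac_bg |> mutate(onset_date = as.Date(NA)),
    reac_tg |> mutate(onset_date = onset)
  ) |>
    mutate(case_version = 1L,
           outcome = sample(outcomes, n(), replace = TRUE, prob = out_p)) |>
    select("report_id", "case_version", "pt", "onset_date", "outcome")

  # exact-content duplicates of target reports under new ids
  n_dup <- round(cfg$duplicate_fraction * n_tg)
  dup_pairs <- tibble(original = character(), duplicate = character())
  if (n_dup > 0) {
    dup_src <- sample(tg_ids, n_dup)
    dup_ids <- sprintf("DU%06d", seq_len(n_dup))
    dup_pairs <- tibble(original = dup_src, duplicate = dup_ids)
    clone <- function(tab) {
      cloned <- tab[match_rows(tab$report_id, dup_src), ]
      cloned$report_id <- dup_ids[match(cloned$report_id0, dup_src)]
      cloned$report_id0 <- NULL
      cloned
    }
    match_rows <- function(ids_col, src) which(ids_col %in% src)
    add_orig <- function(tab) { tab$report_id0 <- tab$report_id; tab }
    reports <- bind_rows(reports, clone(add_orig(reports)))
    drugs <- bind_rows(drugs, clone(add_orig(drugs)))
    reactions <- bind_rows(reactions, clone(add_orig(reactions)))
  }

  store <- report_store(reports, drugs, reactions,
                        provenance = sprintf("synthetic (seed %s)", cfg$seed))

  deduped <- deduplicate(store)
  realized <- build_all_pt_tables(deduped, cfg$target_drug, min_a = 0)
  rr_overall <- setNames(rep(1, length(cat_pt)), cat_pt)
  unrestricted <- !nrow(sig) | (is.na(sig$sex) & is.na(sig$age) & is.na(sig$partner_drug))
  if (nrow(sig)) rr_overall[sig$pt[unrestricted]] <- sig$rr[unrestricted]
  pt_truth <- cfg$pt_catalog |>
    mutate(rr = unname(rr_overall[.data$pt]),
           expected_a = unname(expected_a[.data$pt])) |>
    left_join(realized, by = "pt") |>
    mutate(dplyr::across(c("a", "b", "c", "d"), \(x) replace_na(x, 0)))
  manifest <- list(
    target_drug = cfg$target_drug,
    n_target_reports = n_tg,
    n_background_reports = n_bg,
    n_reports_emitted = nrow(store$reports),
    n_reports_deduplicated = nrow(deduped$reports),
    injected_signals = sig,
    pt_truth = pt_truth,
    duplicates = dup_pairs,
    seed = cfg$seed
  )
  list(store = store, manifest = manifest)
}

#' Replay explicit contingency cells as a minimal report store
#'
#' Emits a store whose 2x2 table for (`target_drug`, `pt`) is exactly
#' (`a`, `b`, `c`, `d`) under the record counting unit. Small cells become
#' unit reports; cells above `max_unit_reports` are encoded as a single
#' aggregated pseudo-record carrying the count as its weight, so replaying a
#' published row with d of tens of millions stays tiny. Used to replay
#' reconstructed published signal-table rows through the full pipeline.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param pt target event PT (cell a/c).
#' @param target_drug exposure drug name.
#' @param other_pt,other_drug names standing for all other events/exposures.
#' @param max_unit_reports cells at or below this emit one report per count.
#' @return a [report_store()].
#' @export
replay_counts <- function(a, b, c, d, pt = "target event",
                          target_drug = "target drug",
                          other_pt = "other event", other_drug = "other drug",
                          max_unit_reports = 1000) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  cells <- tibble(
    cell = c("a", "b", "c", "d"),
    count = c(a, b, c, d),
    drug = c(target_drug, target_drug, other_drug, other_drug),
    event = c(pt, other_pt, pt, other_pt)
  ) |> filter(.data$count > 0)
  mk <- function(cell, count, drug, event) {
    if (count <= max_unit_reports) {
      n <- as.integer(round(count))
      idv <- sprintf("%s%07d", toupper(cell), seq_len(n))
      w <- rep(1, n)
    } else {
      idv <- sprintf("%s0000001", toupper(cell))
      w <- round(count)
    }
    list(
      reports = tibble(report_id = idv, case_version = 1L,
                       receipt_date = as.Date("2024-12-29"), sex = "unknown",
                       age_years = NA_real_, region = "unknown",
                       serious = FALSE, weight = w),
      drugs = tibble(report_id = idv, case_version = 1L, drug_name = drug,
                     role = "suspect", therapy_start = as.Date(NA)),
      reactions = tibble(report_id = idv, case_version = 1L, pt = event,
                         onset_date = as.Date(NA), outcome = "unknown")
    )
  }
  parts <- lapply(seq_len(nrow(cells)), function(i) {
    mk(cells$cell[i], cells$count[i], cells$drug[i], cells$event[i])
  })
  report_store(
    bind_rows(lapply(parts, `[[`, "reports")),
    bind_rows(lapply(parts, `[[`, "drugs")),
    bind_rows(lapply(parts, `[[`, "reactions")),
    provenance = "replayed counts"
  )
}
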