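#' Configure an end-to-end screening run
#'
#' Bundles every input the pipeline needs: where the reports come from (a
#' file/directory path or an in-memory [report_store()]), the exposure drug,
#' the PT-to-SOC hierarchy, thresholds, priors, strata, and the output
#' directory. File paths are validated here, and the combined-rule expression
#' is parsed before any computation starts.
#'
#' @param reports path to a report table (or a [report_store()]).
#' @param dialect `"flat_csv"` or `"faers_ascii"` (ignored for in-memory
#'   stores).
#' @param drug exposure drug name.
#' @param pt2soc path to the two-column PT-to-SOC CSV, or a hierarchy object.
#' @param out_dir output directory (created if absent).
#' @param roles qualifying drug roles.
#' @param thresholds a [threshold_config()] (its `rule` is the combined
#'   signal rule).
#' @param priors a [bcpnn_priors()].
#' @param strata list of [stratum()] objects for the stratified screens.
#' @param label optional path to a label-listed PT file, or character vector.
#' @param synonyms optional drug synonym table.
#' @param ddi_top_k number of co-administration partners to screen.
#' @param tto_event PT for the time-to-onset summary, or `"all"`.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return an object of class `run_config`.
#' @export
run_config <- function(reports, drug, pt2soc, out_dir,
                       dialect = "flat_csv", roles = .role_levels,
                       thresholds = threshold_config(),
                       priors = bcpnn_priors(), strata = default_strata(),
                       label = NULL, synonyms = NULL, ddi_top_k = 8,
                       tto_event = "all", seed = 1L) {
  if (is.character(reports) && !file.exists(reports) && !dir.exists(reports)) {
    abort(sprintf("reports input not found: %s", reports))
  }
  if (is.character(pt2soc) && !file.exists(pt2soc)) {
    abort(sprintf("pt2soc mapping not found: %s", pt2soc))
  }
  if (is.character(label) && length(label) == 1L && file.exists(label)) {
    label <- read_label_list(label)
  }
  parse_rule(thresholds$rule)
  structure(
    list(reports = reports, dialect = dialect, drug = drug, pt2soc = pt2soc,
         out_dir = out_dir, roles = roles, thresholds = thresholds,
         priors = priors, strata = strata, label = label, synonyms = synonyms,
         ddi_top_k = ddi_top_k, tto_event = tto_event, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full screening pipeline
#'
#' Read, deduplicate, select the exposure's reports, then run the overall
#' PT screen, the SOC rollup, the sex/age-stratified screens, the
#' time-to-onset summary, and the co-administration screens, writing one TSV
#' per artifact plus a concordance JSON and a run manifest with the
#' stage-by-stage report counts (the selection-flow ledger). Deterministic
#' given identical inputs and seed.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the artifact paths and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hierarchy <- if (is.character(cfg$pt2soc)) read_pt2soc(cfg$pt2soc) else
    as_hierarchy(cfg$pt2soc)
  store <- if (inherits(cfg$reports, "report_store")) cfg$reports else
    read_reports(cfg$reports, dialect = cfg$dialect)

  stages <- list(raw_reports = nrow(store$reports))
  store <- deduplicate(store)
  stages$deduplicated_reports <- nrow(store$reports)
  target <- select_drug_reports(store, cfg$drug, roles = cfg$roles,
                                synonyms = cfg$synonyms)
  stages$target_drug_reports <- nrow(target$reports)
  stages$target_event_records <- nrow(event_records(target))
  message(sprintf("[pipeline] raw=%d dedup=%d target=%d records=%d",
                  stages$raw_reports, stages$deduplicated_reports,
                  stages$target_drug_reports, stages$target_event_records))

  paths <- list()
  overall <- screen_pt(store, cfg$drug, hierarchy, thresholds = cfg$thresholds,
                       priors = cfg$priors, label = cfg$label,
                       roles = cfg$roles, synonyms = cfg$synonyms)
  if (!is.null(cfg$label)) overall <- flag_unlisted(overall, cfg$label)
  paths$screen_overall <- file.path(cfg$out_dir, "screen_overall.tsv")
  write_screen_tsv(overall, paths$screen_overall)

  rollup <- soc_rollup(store, cfg$drug, hierarchy, roles = cfg$roles,
                       synonyms = cfg$synonyms)
  paths$soc_rollup <- file.path(cfg$out_dir, "soc_rollup.tsv")
  readr::write_tsv(rollup, paths$soc_rollup, progress = FALSE)

  strat <- stratified_screen(store, cfg$drug, hierarchy,
                             thresholds = cfg$thresholds, priors = cfg$priors,
                             strata = cfg$strata, label = cfg$label,
                             roles = cfg$roles, synonyms = cfg$synonyms)
  for (nm in names(strat$screens)) {
    p <- file.path(cfg$out_dir,
                   sprintf("screen_%s.tsv", gsub("[^a-z0-9]+", "_", nm)))
    write_screen_tsv(strat$screens[[nm]], p)
    paths[[paste0("screen_", nm)]] <- p
  }
  paths$stratum_comparison <- file.path(cfg$out_dir, "stratum_comparison.tsv")
  readr::write_tsv(strat$comparison, paths$stratum_comparison, progress = FALSE)

  tto <- tto_summary(store, cfg$drug, event = cfg$tto_event,
                     roles = cfg$roles, synonyms = cfg$synonyms)
  paths$tto <- file.path(cfg$out_dir, "tto.tsv")
  write_tto_tsv(tto, paths$tto)

  partners <- top_partners(store, cfg$drug, k = cfg$ddi_top_k,
                           roles = cfg$roles, synonyms = cfg$synonyms)
  paths$ddi_partners <- file.path(cfg$out_dir, "ddi_partners.tsv")
  readr::write_tsv(partners, paths$ddi_partners, progress = FALSE)
  ddi_rows <- lapply(partners$partner, function(p) {
    res <- combination_screen(store, combination_exposure(cfg$drug, p),
                              hierarchy, thresholds = cfg$thresholds,
                              priors = cfg$priors, roles = cfg$roles,
                              synonyms = cfg$synonyms)
    if (nrow(res$rows) == 0L) return(NULL)
    res$rows |>
      mutate(partner = p) |>
      select("partner", "soc", "pt", "a", "ror", "ror_lo", "ror_hi", "positive",
             "base_drug_positive", "combination_specific")
  })
  ddi_tab <- bind_rows(ddi_rows)
  paths$ddi_screen <- file.path(cfg$out_dir, "ddi_screen.tsv")
  readr::write_tsv(
    if (nrow(ddi_tab)) ddi_tab |> mutate(dplyr::across(
      c("ror", "ror_lo", "ror_hi"), \(x) round_half_up(x, 2))) else ddi_tab,
    paths$ddi_screen, progress = FALSE)

  conc <- concordance(overall)
  paths$concordance <- file.path(cfg$out_dir, "concordance.json")
  jsonlite::write_json(conc, paths$concordance, digits = NA, pretty = TRUE)

  manifest <- list(
    drug = cfg$drug,
    rule = cfg$thresholds$rule,
    seed = cfg$seed,
    stages = stages,
    n_pt_tested = overall$meta$n_pt_tested,
    n_positive = overall$meta$n_positive,
    n_soc_positive = overall$meta$n_soc_positive,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pvscreen")),
    config_hash = unname(tools::md5sum(
      write_config_json(cfg, file.path(cfg$out_dir, "run_config.json"))))
  )
  paths$manifest <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest, overall = overall,
                 stratified = strat, tto = tto, partners = partners))
}

# serialize the reproducible part of a run config for hashing
write_config_json <- function(cfg, path) {
  ser <- list(
    reports = if (is.character(cfg$reports)) cfg$reports else "in-memory store",
    dialect = cfg$dialect, drug = cfg$drug,
    pt2soc = if (is.character(cfg$pt2soc)) cfg$pt2soc else "in-memory hierarchy",
    roles = cfg$roles,
    thresholds = unclass(cfg$thresholds),
    priors = unclass(cfg$priors),
    strata = lapply(cfg$strata, unclass),
    label = cfg$label, ddi_top_k = cfg$ddi_top_k,
    tto_event = cfg$tto_event, seed = cfg$seed
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}
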