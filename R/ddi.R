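#' Define a co-administration (combination) exposure
#'
#' @param base_drug the target drug.
#' @param partner_drug the co-administered drug; must differ from the base
#'   after name normalization.
#' @param synonyms optional drug synonym table.
#' @return an object of class `combination_exposure`.
#' @export
combination_exposure <- function(base_drug, partner_drug, synonyms = NULL) {
  if (identical(resolve_drug_name(base_drug, synonyms),
                resolve_drug_name(partner_drug, synonyms))) {
    abort("base and partner drug must differ after normalization")
  }
  structure(list(base_drug = base_drug, partner_drug = partner_drug),
            class = "combination_exposure")
}

#' Most frequent co-administered partners of a drug
#'
#' Partners are ranked by the number of reports containing both the base drug
#' and the partner (any role by default), ties broken alphabetically.
#'
#' @param store a deduplicated [report_store()].
#' @param base_drug the target drug.
#' @param k number of partners to return.
#' @param roles roles qualifying the *base* drug match (partners match any
#'   role unless `partner_roles` narrows them).
#' @param partner_roles roles qualifying the partner match.
#' @param synonyms optional drug synonym table.
#' @return tibble with `partner`, `n_reports`, at most `k` rows.
#' @export
top_partners <- function(store, base_drug, k = 8, roles = .role_levels,
                         partner_roles = .role_levels, synonyms = NULL) {
  stopifnot(k >= 1)
  base_ids <- exposed_report_ids(store, base_drug, roles, synonyms)
  if (!length(base_ids)) {
    return(tibble(partner = character(), n_reports = numeric()))
  }
  base_norm <- resolve_drug_name(base_drug, synonyms)
  partners <- store$drugs |>
    filter(.data$report_id %in% base_ids, .data$role %in% partner_roles) |>
    mutate(partner = resolve_drug_name(.data$drug_norm, synonyms)) |>
    filter(.data$partner != base_norm) |>
    distinct(.data$report_id, .data$partner) |>
    inner_join(store$reports |> select("report_id", "weight"), by = "report_id") |>
    group_by(.data$partner) |>
    summarise(n_reports = sum(.data$weight), .groups = "drop") |>
    arrange(desc(.data$n_reports), .data$partner)
  head(partners, k)
}

#' Disproportionality screen for a drug combination
#'
#' Exposure = reports containing both drugs; comparator = all other reports
#' (including base-drug-only reports). The same statistics, thresholds and
#' ranking as [screen_pt()] apply. Each PT additionally carries
#' `base_drug_positive`: whether the base-drug-alone screen also flags it —
#' signals positive for the combination but not the base alone are candidate
#' interaction (DDI) signals.
#'
#' @param store a deduplicated [report_store()].
#' @param combo a [combination_exposure()].
#' @param hierarchy PT-to-SOC mapping.
#' @param thresholds a [threshold_config()].
#' @param priors a [bcpnn_priors()].
#' @param roles roles qualifying the base-drug match.
#' @param synonyms optional drug synonym table.
#' @return a `screen_result` whose rows carry `base_drug_positive` and
#'   `combination_specific` columns.
#' @export
combination_screen <- function(store, combo, hierarchy,
                               thresholds = threshold_config(),
                               priors = bcpnn_priors(),
                               roles = .role_levels, synonyms = NULL) {
  stopifnot(inherits(combo, "combination_exposure"))
  n_combo <- length(exposure_ids(store, combo, roles, synonyms))
  res <- screen_pt(store, combo, hierarchy, thresholds = thresholds,
                   priors = priors, roles = roles, synonyms = synonyms)
  res$meta$n_combo_reports <- n_combo
  res$meta$degenerate <- res$meta$degenerate || n_combo == 0L
  base_res <- screen_pt(store, combo$base_drug, hierarchy,
                        thresholds = thresholds, priors = priors,
                        roles = roles, synonyms = synonyms)
  base_pos <- base_res$rows |> select("pt", base_drug_positive = "positive")
  res$rows <- res$rows |>
    left_join(base_pos, by = "pt") |>
    mutate(base_drug_positive = replace_na(.data$base_drug_positive, FALSE),
           combination_specific = .data$positive & !.data$base_drug_positive)
  res
}
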