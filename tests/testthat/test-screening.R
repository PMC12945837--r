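test_that("an injected signal is flagged and dominates the null ranking", {
  catalog <- uniform_catalog(100) # p = 0.01 each
  cfg <- small_config(seed = 21, n_target_reports = 300,
                      n_background_records = 3e4, pt_catalog = catalog,
                      injected_signals = tibble::tibble(
                        pt = "npt050", rr = 10, sex = NA_character_,
                        age = NA_character_, partner_drug = NA_character_))
  sim <- generate_reports(cfg)
  store <- deduplicate(sim$store)
  hier <- as_hierarchy(catalog[, c("pt", "soc")])
  res <- screen_pt(store, "ublituximab", hier)
  sig <- res$rows[res$rows$pt == "npt050", ]
  expect_true(sig$positive)
  expect_equal(res$rows$pt[1], "npt050") # strongest ROR
  # null PTs stay near the nominal false-positive rate of the combined rule
  nulls <- res$rows[res$rows$pt != "npt050", ]
  expect_lte(mean(nulls$positive), 0.075)
  expect_gte(res$meta$n_positive, 1)
})

test_that("an unattainable case floor empties the screen", {
  store <- random_store(n = 40, seed = 2)
  res <- screen_pt(store, "targetdrug", hier_for(store),
                   thresholds = threshold_config(min_a = 1e6))
  expect_equal(nrow(res$rows), 0L)
  expect_true(res$meta$degenerate)
  expect_equal(res$meta$n_positive, 0)
})

test_that("five-method concordant PTs are a subset of each single method's set", {
  store <- random_store(n = 100, n_pt = 6, seed = 9)
  res <- screen_pt(store, "targetdrug", hier_for(store),
                   thresholds = threshold_config(min_a = 1))
  all5 <- res$rows$flag_ror & res$rows$flag_prr & res$rows$flag_mhra &
    res$rows$flag_bcpnn & res$rows$flag_ebgm
  expect_true(all(!all5 | res$rows$flag_ror))
  co <- concordance(res)
  expect_equal(co$n_at_least[co$methods == "ror+prr+mhra+bcpnn+ebgm"],
               sum(all5))
})

test_that("concordance matches a brute-force power-set enumeration", {
  set.seed(31)
  methods <- c("ror", "prr", "mhra", "bcpnn", "ebgm")
  flags <- matrix(runif(20 * 5) < 0.4, nrow = 20,
                  dimnames = list(NULL, methods))
  fake <- structure(list(rows = tibble::as_tibble(
    stats::setNames(as.data.frame(flags), paste0("flag_", methods)))),
    class = "screen_result")
  co <- concordance(fake)
  for (i in seq_len(nrow(co))) {
    s <- strsplit(co$methods[i], "+", fixed = TRUE)[[1]]
    in_s <- rowSums(flags[, s, drop = FALSE]) == length(s)
    out_s <- rowSums(flags[, setdiff(methods, s), drop = FALSE]) == 0
    expect_equal(co$n_at_least[i], sum(in_s))
    expect_equal(co$n_exactly[i], sum(in_s & out_s))
  }
  # exactly-counts over all non-empty subsets partition the flagged rows
  expect_equal(sum(co$n_exactly), sum(rowSums(flags) > 0))
})

test_that("label listedness splits positive signals as constructed", {
  catalog <- uniform_catalog(50)
  cfg <- small_config(seed = 13, n_target_reports = 400,
                      n_background_records = 2e4, pt_catalog = catalog,
                      injected_signals = tibble::tibble(
                        pt = c("npt010", "npt020"), rr = 10,
                        sex = NA_character_, age = NA_character_,
                        partner_drug = NA_character_))
  store <- generate_reports(cfg)$store
  res <- screen_pt(store, "ublituximab",
                   as_hierarchy(catalog[, c("pt", "soc")]))
  pos <- res$rows$pt[res$rows$positive]
  expect_true(all(c("npt010", "npt020") %in% pos))
  all_listed <- flag_unlisted(res, label = res$rows$pt)
  expect_equal(all_listed$meta$n_unlisted, 0)
  none_listed <- flag_unlisted(res, label = "unrelated_pt")
  expect_equal(none_listed$meta$n_unlisted, length(pos))
  # a fixture with a known number of unlisted positives reports exactly that
  unlisted_set <- pos[1]
  partial <- flag_unlisted(res, label = setdiff(res$rows$pt, unlisted_set))
  expect_equal(partial$meta$n_unlisted, length(unlisted_set))
  expect_error(flag_unlisted(res, label = character(0)), "non-empty")
})

test_that("SOC rollup proportions are exhaustive and normalized", {
  one_soc <- mk_store(rpt("R1", c("ptA", "ptB"), drugs = "targetdrug"),
                      rpt("R2", "ptA", drugs = "targetdrug"),
                      rpt("R3", "ptC", drugs = "otherdrug"))
  hier1 <- as_hierarchy(tibble::tibble(pt = c("ptA", "ptB", "ptC"),
                                       soc = "socX"))
  ru <- soc_rollup(one_soc, "targetdrug", hier1)
  expect_equal(ru$proportion, 1)
  expect_equal(ru$records, 3)
  # generator SOC mix is recovered within multinomial error
  catalog <- tibble::tibble(pt = sprintf("p%02d", 1:10),
                            soc = rep(c("socA", "socB"), c(3, 7)),
                            background_probability = rep(c(0.34 / 3, 0.66 / 7),
                                                         c(3, 7)))
  sim <- generate_reports(small_config(seed = 17, pt_catalog = catalog,
                                       n_target_reports = 800))
  ru2 <- soc_rollup(sim$store, "ublituximab",
                    as_hierarchy(catalog[, c("pt", "soc")]))
  expect_equal(sum(ru2$proportion), 1, tolerance = 1e-9)
  expect_equal(ru2$proportion[ru2$soc == "socB"], 0.66, tolerance = 0.05)
})

test_that("screens are deterministic and stable under input row permutation", {
  store <- random_store(n = 80, n_pt = 6, seed = 23)
  hier <- hier_for(store)
  res1 <- screen_pt(store, "targetdrug", hier)
  f1 <- file.path(tempdir(), "screen_a.tsv")
  f2 <- file.path(tempdir(), "screen_b.tsv")
  write_screen_tsv(res1, f1)
  write_screen_tsv(screen_pt(store, "targetdrug", hier), f2)
  expect_identical(readLines(f1), readLines(f2))
  # permute the underlying tables: same ranked output
  perm <- store
  set.seed(1)
  perm$reports <- perm$reports[sample(nrow(perm$reports)), ]
  perm$drugs <- perm$drugs[sample(nrow(perm$drugs)), ]
  perm$reactions <- perm$reactions[sample(nrow(perm$reactions)), ]
  write_screen_tsv(screen_pt(perm, "targetdrug", hier), f2)
  expect_identical(readLines(f1), readLines(f2))
})
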