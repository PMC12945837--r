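#' BCPNN credibility priors
#'
#' Prior constants of the closed-form Bayesian confidence propagation neural
#' network information component. The defaults (`gamma11 = 1`,
#' `alpha1 = beta1 = 1`, `alpha = beta = 2`) are the canonical values of the
#' BCPNN literature; the dependence prior `gamma` is derived from them so the
#' prior expectation of the IC is zero.
#'
#' @param gamma11,alpha1,beta1,alpha,beta positive reals.
#' @return an object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1, alpha = 2, beta = 2) {
  vals <- c(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  if (any(vals <= 0)) abort("all BCPNN priors must be positive")
  structure(as.list(vals), class = "bcpnn_priors")
}

#' Signal-screening thresholds
#'
#' The per-method signal criteria: ROR and PRR flag when `a >= min_a` and the
#' 95% CI lower limit exceeds 1; MHRA when `PRR >= prr_min`, `chi2 >=
#' chi2_min` and `a >= 3`; BCPNN when `IC - 2SD > 0` (the IC025 credibility
#' bound); EBGM when `EBGM05 > ebgm_lo_min`.
#'
#' @param min_a minimum case count (default 3).
#' @param z normal quantile for the 95% intervals (default 1.96).
#' @param prr_min,chi2_min MHRA criterion cutoffs (defaults 2 and 4).
#' @param ebgm_lo_min EBGM05 cutoff (default 2).
#' @param rule boolean expression over `ror`, `prr`, `mhra`, `bcpnn`, `ebgm`
#'   defining a combined "positive signal" (default `"ror & prr"`).
#' @param continuity apply the Haldane-Anscombe +0.5 correction to zero cells
#'   instead of returning undefined statistics (default `FALSE`).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(min_a = 3, z = 1.96, prr_min = 2, chi2_min = 4,
                             ebgm_lo_min = 2, rule = "ror & prr",
                             continuity = FALSE) {
  stopifnot(min_a >= 1, z > 0, prr_min > 0, chi2_min > 0, ebgm_lo_min > 0)
  parse_rule(rule) # validate before any computation
  structure(list(min_a = min_a, z = z, prr_min = prr_min, chi2_min = chi2_min,
                 ebgm_lo_min = ebgm_lo_min, rule = rule,
                 continuity = continuity),
            class = "threshold_config")
}

# Parse and validate a combined-rule expression over the five method names.
parse_rule <- function(rule) {
  expr <- tryCatch(str2lang(rule), error = function(e) {
    abort(sprintf("malformed rule expression: %s", rule))
  })
  allowed <- c("ror", "prr", "mhra", "bcpnn", "ebgm",
               "&", "|", "!", "(", "&&", "||")
  seen <- all.names(expr, unique = TRUE)
  bad <- setdiff(seen, allowed)
  if (length(bad)) {
    abort(sprintf("rule expression may only use {ror, prr, mhra, bcpnn, ebgm} and & | ! (): offending token(s) %s",
                  paste(bad, collapse = ", ")))
  }
  expr
}

cells_of <- function(t) {
  if (inherits(t, "contingency_table")) {
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  } else {
    stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
    list(a = t[["a"]], b = t[["b"]], c = t[["c"]], d = t[["d"]])
  }
}

# Vectorized engine over cell vectors; every user-facing compute_* wraps this.
# Zero cells: without the continuity correction any statistic whose formula
# divides by (or takes log of) an empty cell is returned NA with a reason.
dispro_engine <- function(a, b, c, d, z = 1.96, priors = bcpnn_priors(),
                          continuity = FALSE) {
  # doubles throughout: integer cells overflow in the chi-square denominator
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  needs_cc <- a <= 0 | b <= 0 | c <= 0 | d <= 0
  reason <- ifelse(needs_cc & !continuity, "zero cell", NA_character_)
  if (continuity) {
    a <- ifelse(needs_cc, a + 0.5, a)
    b <- ifelse(needs_cc, b + 0.5, b)
    c <- ifelse(needs_cc, c + 0.5, c)
    d <- ifelse(needs_cc, d + 0.5, d)
  }
  n <- a + b + c + d
  ok <- is.na(reason)
  safe <- function(x) ifelse(ok, x, NA_real_)

  se_ln <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- a * d / (b * c)
  ror_lo <- exp(log(ror) - z * se_ln)
  ror_hi <- exp(log(ror) + z * se_ln)

  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_lo <- exp(log(prr) - z * se_prr)
  prr_hi <- exp(log(prr) + z * se_prr)
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (a + c) * (c + d) * (b + d))

  ebgm <- a * n / ((a + c) * (a + b))
  ebgm_lo <- exp(log(ebgm) - z * se_ln)
  ebgm_hi <- exp(log(ebgm) + z * se_ln)
  ic <- log2(ebgm) # identical expression: log2[a N / ((a+b)(a+c))]

  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gam) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
    (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
    (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))
  )
  ic_minus_2sd <- e_ic - 2 * sqrt(v_ic)
  bad_ic <- !is.finite(e_ic) | !is.finite(v_ic)
  if (any(bad_ic & ok)) {
    abort("non-finite BCPNN intermediate (E(IC) or V(IC)); check the table cells")
  }

  tibble(
    a = a, b = b, c = c, d = d, n = n,
    ror = safe(ror), ror_lo = safe(ror_lo), ror_hi = safe(ror_hi),
    prr = safe(prr), prr_lo = safe(prr_lo), prr_hi = safe(prr_hi),
    chi2 = safe(chi2),
    ic = ifelse(a > 0, ic, NA_real_),
    e_ic = ifelse(a > 0, e_ic, NA_real_),
    v_ic = ifelse(a > 0, v_ic, NA_real_),
    ic_minus_2sd = ifelse(a > 0, ic_minus_2sd, NA_real_),
    ebgm = ifelse(a > 0, ebgm, NA_real_),
    ebgm_lo = safe(ebgm_lo), ebgm_hi = safe(ebgm_hi),
    undefined_reason = reason
  )
}

#' Reporting odds ratio with lognormal confidence interval
#'
#' `ROR = ad / bc`, with 95% CI `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))`.
#'
#' @param t a `contingency_table` (or list with `a`, `b`, `c`, `d`).
#' @param z normal quantile (default 1.96).
#' @param continuity apply +0.5 to all cells when any is zero.
#' @return list with `ror`, `ror_lo`, `ror_hi` (and `undefined_reason`, `NA`
#'   unless a zero cell made the statistic undefined).
#' @export
compute_ror <- function(t, z = 1.96, continuity = FALSE) {
  x <- cells_of(t)
  m <- dispro_engine(x$a, x$b, x$c, x$d, z = z, continuity = continuity)
  list(ror = m$ror, ror_lo = m$ror_lo, ror_hi = m$ror_hi,
       undefined_reason = m$undefined_reason)
}

#' Proportional reporting ratio, its CI, and the chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with CI `exp(ln PRR +/- z * sqrt(1/a -
#' 1/(a+b) + 1/c - 1/(c+d)))`; the companion chi-square (no continuity
#' correction) is `(ad - bc)^2 N / [(a+b)(a+c)(c+d)(b+d)]`.
#'
#' @inheritParams compute_ror
#' @return list with `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
compute_prr <- function(t, z = 1.96, continuity = FALSE) {
  x <- cells_of(t)
  m <- dispro_engine(x$a, x$b, x$c, x$d, z = z, continuity = continuity)
  list(prr = m$prr, prr_lo = m$prr_lo, prr_hi = m$prr_hi, chi2 = m$chi2,
       undefined_reason = m$undefined_reason)
}

#' BCPNN information component with closed-form credibility bound
#'
#' The observed IC is `log2[a N / ((a+b)(a+c))]`. Its posterior expectation
#' `E(IC)` and variance `V(IC)` use the closed-form beta/gamma approximation
#' with the dependence prior `gamma` derived from the independence priors;
#' the lower credibility bound is `IC - 2SD = E(IC) - 2 sqrt(V(IC))` (the
#' IC025 used for signal flagging).
#'
#' @inheritParams compute_ror
#' @param priors a [bcpnn_priors()].
#' @return list with `ic`, `e_ic`, `v_ic`, `ic_minus_2sd`.
#' @export
compute_bcpnn <- function(t, priors = bcpnn_priors()) {
  x <- cells_of(t)
  if (any(x$a < 1)) abort("BCPNN requires a >= 1")
  m <- dispro_engine(x$a, x$b, x$c, x$d, priors = priors)
  list(ic = m$ic, e_ic = m$e_ic, v_ic = m$v_ic, ic_minus_2sd = m$ic_minus_2sd)
}

#' EBGM relative reporting ratio with lognormal interval
#'
#' Implemented exactly as the screening literature's crude relative reporting
#' ratio `EBGM = a N / ((a+c)(a+b))` with the same lognormal standard error as
#' the ROR — not the full gamma-Poisson mixture fit. `EBGM05` is the interval's
#' lower limit. Note `IC = log2(EBGM)` by construction.
#'
#' @inheritParams compute_ror
#' @return list with `ebgm`, `ebgm_lo` (EBGM05), `ebgm_hi`.
#' @export
compute_ebgm <- function(t, z = 1.96) {
  x <- cells_of(t)
  if (any(x$a < 1)) abort("EBGM requires a >= 1")
  m <- dispro_engine(x$a, x$b, x$c, x$d, z = z)
  list(ebgm = m$ebgm, ebgm_lo = m$ebgm_lo, ebgm_hi = m$ebgm_hi,
       undefined_reason = m$undefined_reason)
}

#' All disproportionality statistics for one table
#'
#' @inheritParams compute_ror
#' @param priors a [bcpnn_priors()].
#' @param cfg a [threshold_config()]; also controls the continuity correction.
#' @return one-row tibble with the cells, every statistic and bound, the
#'   per-method signal flags (`flag_ror`, `flag_prr`, `flag_mhra`,
#'   `flag_bcpnn`, `flag_ebgm`), and the combined `positive` flag.
#' @export
signal_metrics <- function(t, priors = bcpnn_priors(), cfg = threshold_config()) {
  x <- cells_of(t)
  m <- dispro_engine(x$a, x$b, x$c, x$d, z = cfg$z, priors = priors,
                     continuity = cfg$continuity)
  add_flags(m, cfg)
}

# flag columns from a metrics tibble; undefined statistics flag FALSE
add_flags <- function(m, cfg) {
  flag_na_false <- function(x) !is.na(x) & x
  m$flag_ror <- flag_na_false(m$a >= cfg$min_a & m$ror_lo > 1)
  m$flag_prr <- flag_na_false(m$a >= cfg$min_a & m$prr_lo > 1)
  m$flag_mhra <- flag_na_false(m$prr >= cfg$prr_min & m$chi2 >= cfg$chi2_min &
                                 m$a >= 3)
  m$flag_bcpnn <- flag_na_false(m$ic_minus_2sd > 0)
  m$flag_ebgm <- flag_na_false(m$ebgm_lo > cfg$ebgm_lo_min)
  expr <- parse_rule(cfg$rule)
  env <- list(ror = m$flag_ror, prr = m$flag_prr, mhra = m$flag_mhra,
              bcpnn = m$flag_bcpnn, ebgm = m$flag_ebgm)
  m$positive <- eval(expr, envir = env)
  m
}

#' Evaluate the per-method signal flags for precomputed metrics
#'
#' @param m one-row metrics tibble (as from [signal_metrics()]) or list with
#'   fields `ror_lo`, `prr`, `prr_lo`, `chi2`, `ic_minus_2sd`, `ebgm_lo`.
#' @param a case count of the pair.
#' @param cfg a [threshold_config()].
#' @return named logical vector over the five methods.
#' @export
evaluate_flags <- function(m, a, cfg = threshold_config()) {
  row <- tibble(a = a,
                ror_lo = m$ror_lo %||% NA_real_,
                prr = m$prr %||% NA_real_,
                prr_lo = m$prr_lo %||% NA_real_,
                chi2 = m$chi2 %||% NA_real_,
                ic_minus_2sd = m$ic_minus_2sd %||% NA_real_,
                ebgm_lo = m$ebgm_lo %||% NA_real_)
  f <- add_flags(row, cfg)
  c(ror = f$flag_ror, prr = f$flag_prr, mhra = f$flag_mhra,
    bcpnn = f$flag_bcpnn, ebgm = f$flag_ebgm)
}
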