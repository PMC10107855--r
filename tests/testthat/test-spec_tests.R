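fake_fit <- function(coefs, ses, df = 50, outcome = "le",
                     class2 = "hfs_fefit") {
  structure(list(coefficients = coefs, se = ses,
                 vcov = diag(ses^2, length(ses)) |>
                   `dimnames<-`(list(names(coefs), names(coefs))),
                 df = df, outcome = outcome),
            class = unique(c(class2, "hfs_fefit")))
}

test_that("Clogg statistic is zero on identical fits and follows Eq arithmetic", {
  f1 <- fake_fit(c(SHI = 0.5, GOV = 1.2), c(SHI = 0.3, GOV = 0.4))
  f2 <- fake_fit(c(SHI = 0.5, GOV = 1.2), c(SHI = 0.3, GOV = 0.4),
                 class2 = "hfs_trendfit")
  t0 <- clogg_test(f1, f2, "GOV")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # difference 1 with SEs (0.6, 0.8): Z = 1 / sqrt(0.36 + 0.64) = 1
  fa <- fake_fit(c(GOV = 1.0, SHI = 0), c(GOV = 0.6, SHI = 1))
  fb <- fake_fit(c(GOV = 2.0, SHI = 0), c(GOV = 0.8, SHI = 1),
                 class2 = "hfs_trendfit")
  t1 <- clogg_test(fa, fb, "GOV")
  expect_equal(t1$statistic, 1.0)
  expect_equal(t1$p_value, 2 * pnorm(-1))

  fc <- fb; fc$outcome <- "cat10"
  expect_error(clogg_test(fa, fc, "GOV"), "different outcomes")
})

test_that("the ratio restriction test handles nulls, oracles and degeneracy", {
  mk <- function(rhot, betat, Vd = NULL) {
    nm <- c(paste0("GOV:y", 2:4), paste0("y", 2:4))
    b <- c(rhot, betat); names(b) <- nm
    V <- if (is.null(Vd)) diag(0.01, 6) else Vd
    dimnames(V) <- list(nm, nm)
    structure(list(coefficients = b, vcov = V, df = 40, year_levels = 1:4,
                   year_terms = paste0("y", 2:4),
                   interaction_terms = list(GOV = paste0("GOV:y", 2:4))),
              class = c("hfs_difftrend", "hfs_fefit"))
  }
  # all rho_t = 0: ratio 0, p = 1
  t0 <- pta_ratio_test(mk(c(0, 0, 0), c(1, 2, 3)), "GOV")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$components$ratio, 0)

  # delta-method variance equals the finite-difference jacobian oracle
  set.seed(4)
  A <- matrix(rnorm(36), 6); V <- crossprod(A) / 50
  fit <- mk(c(0.2, -0.1, 0.3), c(1, 1.5, 2), Vd = V)
  tr <- pta_ratio_test(fit, "GOV")
  b <- fit$coefficients
  g <- function(b) sum(b[1:3]) / sum(b[4:6])
  h <- 1e-6
  grad <- vapply(1:6, function(j) {
    e <- numeric(6); e[j] <- h
    (g(b + e) - g(b - e)) / (2 * h)
  }, numeric(1))
  se_oracle <- sqrt(drop(t(grad) %*% V %*% grad))
  expect_equal(tr$components$se_ratio, se_oracle, tolerance = 1e-6)
  expect_equal(tr$statistic, (g(b) / se_oracle)^2, tolerance = 1e-5)

  # near-zero denominator: numerator-only fallback, labelled
  td <- pta_ratio_test(mk(c(0.2, 0.2, 0.2), c(1e-9, -1e-9, 0)), "GOV")
  expect_match(td$note, "denominator")
  expect_true(is.na(td$components$ratio))
})

test_that("lead tests flag anticipation and refuse degenerate panels", {
  sim <- small_sim_panel(seed = 71, n = 40, gov_sw = 10, shi_sw = 3)
  lt <- lead_test(sim$panel, "le", "twfe", controls = "log_gdp_pc")
  expect_named(lt, c("SHI", "GOV"))
  expect_true(all(vapply(lt, function(x) x$p_value >= 0 & x$p_value <= 1,
                         logical(1))))
  # trend and difftrend variants run too
  expect_silent(lead_test(sim$panel, "le", "trend"))
  expect_silent(lead_test(sim$panel, "le", "difftrend"))

  one_year <- sim$panel[sim$panel$year == 2005, ]
  expect_error(lead_test(one_year, "le", "twfe"), "single-year")

  # anticipation planted one year ahead: lead coefficient picks it up
  op <- default_outcome_params()
  op$error_sd[op$outcome == "le"] <- 0.05
  cfg <- sim_config(n_countries = 60, n_gov_switchers = 15,
                    n_shi_switchers = 0, anticipation_frac = 1,
                    outcome_params = op, seed = 77)
  p <- simulate_panel(cfg)$panel
  p$SHI <- p$SHI_true; p$GOV <- p$GOV_true
  lt2 <- lead_test(p, "le", "twfe", treatments = "GOV")
  expect_lt(lt2$GOV$p_value, 0.01)
})

test_that("coefficient-difference test follows its closed form", {
  V <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("SHI", "GOV"),
                                                    c("SHI", "GOV")))
  f <- structure(list(coefficients = c(SHI = 2, GOV = 1), vcov = V, df = 30),
                 class = "hfs_fefit")
  tt <- coef_diff_test(f, c("SHI", "GOV"))
  expect_equal(tt$components$difference, 1)
  expect_equal(tt$components$se, 1)       # sqrt(1 + 1 - 2*0.5)
  expect_equal(tt$statistic, 1)

  f$coefficients <- c(SHI = 1, GOV = 1)
  t0 <- coef_diff_test(f, c("SHI", "GOV"))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
})

test_that("Goodman-Bacon weights sum to one and reproduce the TWFE estimand", {
  for (s in 1:6) {
    sim <- small_sim_panel(seed = 200 + s, n = 40, gov_sw = 10, shi_sw = 0)
    p <- sim$panel
    b <- bacon_weights(p, p$regime_true, "le", which = "GOV")
    expect_equal(sum(b$weights$weight), 1, tolerance = 1e-9)
    expect_equal(b$weighted_sum, b$twfe, tolerance = 1e-8)
    expect_true(all(b$weights$weight >= 0))
    expect_true(b$problematic_share >= 0 && b$problematic_share < 1)
  }

  # brute-force oracle on one panel: TWFE via lm on the restricted sample
  sim <- small_sim_panel(seed = 300, n = 30, gov_sw = 8, shi_sw = 0)
  p <- sim$panel
  b <- bacon_weights(p, p$regime_true, "le", which = "GOV")
  keep_ids <- vapply(split(p, p$country_id), function(g) {
    tr <- g$regime_true == "GOV"
    (!any(tr) && all(g$regime_true == "OOP")) ||
      (any(tr) && !all(tr) && all(g$regime_true[!tr] == "OOP") &&
         all(diff(tr) >= 0))
  }, logical(1))
  sub <- p[p$country_id %in% names(keep_ids)[keep_ids], ]
  sub$D <- as.numeric(sub$regime_true == "GOV")
  oracle <- stats::coef(stats::lm(le ~ D + factor(year) + factor(country_id),
                                  data = sub))["D"]
  expect_equal(b$twfe, unname(oracle), tolerance = 1e-8)
  expect_equal(b$weighted_sum, unname(oracle), tolerance = 1e-8)
})

test_that("a single cohort against never-treated has no problematic weight", {
  # 6 countries: 3 never-treated, 3 switching together in 2006
  yrs <- 2000:2010
  ids <- sprintf("C%d", 1:6)
  p <- expand.grid(country_id = ids, year = yrs, stringsAsFactors = FALSE)
  p <- p[order(p$country_id, p$year), ]
  p$lab <- ifelse(p$country_id %in% ids[1:3] & p$year >= 2006, "GOV", "OOP")
  set.seed(8)
  p$le <- 65 + 2 * (p$lab == "GOV") + rnorm(nrow(p), 0, 0.5) +
    rep(rnorm(6, 0, 3), each = length(yrs))
  b <- bacon_weights(p, p$lab, "le", which = "GOV")
  expect_equal(unique(b$weights$comparison), "treated_vs_never")
  expect_equal(b$problematic_share, 0)
  expect_equal(sum(b$weights$weight), 1, tolerance = 1e-12)

  # fewer than 2 timing groups is refused
  p0 <- p; p0$lab <- "OOP"
  expect_error(bacon_weights(p0, p0$lab, "le", "GOV"), "timing groups")
})

test_that("p-value summaries count bins and significance shares", {
  h <- pvalue_histogram(rep(1, 10))
  expect_equal(h$table$count[10], 10)
  expect_equal(sum(h$table$count), 10)
  expect_equal(h$share_below_05, 0)

  pv <- c(runif(31, 0.2, 1), rep(0.01, 5))
  h2 <- pvalue_histogram(pv)
  expect_equal(h2$n, 36)
  expect_equal(round(100 * (1 - h2$share_below_05)), 86)

  # uniform p-values fill bins evenly within binomial tolerance
  set.seed(12)
  pu <- runif(2000)
  h3 <- pvalue_histogram(pu)
  expect_true(all(abs(h3$table$count - 200) < 5 * sqrt(2000 * 0.1 * 0.9)))

  expect_error(pvalue_histogram(numeric()), "no p-values")
})
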