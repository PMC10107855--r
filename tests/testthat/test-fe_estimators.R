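test_that("within estimator equals the dummy-variable OLS oracle", {
  for (s in 1:4) {
    sim <- small_sim_panel(seed = 100 + s, n = 25, gov_sw = 6, shi_sw = 2)
    p <- sim$panel
    rhs <- c("SHI", "GOV", "log_gdp_pc", "urban_pct")
    f <- fit_twfe(p, "le", controls = c("log_gdp_pc", "urban_pct"))
    oracle <- dummy_ols_coefs(p, "le", rhs)
    expect_lt(max(abs(f$coefficients[rhs] - oracle)), 1e-8)
  }
})

test_that("a 2x2 hand-solved panel is reproduced exactly", {
  # 2 countries x 2 years; treated country switches in year 2:
  # DiD = (y_A2 - y_A1) - (y_B2 - y_B1) = (8 - 5) - (4 - 3) = 2
  p <- data.frame(country_id = c("A", "A", "B", "B"),
                  year = c(1, 2, 1, 2),
                  GOV = c(0, 1, 0, 0), SHI = 0,
                  y = c(5, 8, 3, 4))
  f <- fit_twfe(p, "y", treatments = "GOV")
  expect_equal(unname(f$coefficients["GOV"]), 2, tolerance = 1e-10)
})

test_that("missing cells are deleted listwise per fitted model", {
  sim <- small_sim_panel(seed = 3, n = 20, gov_sw = 5, shi_sw = 2)
  p <- sim$panel
  p$gini[1:30] <- NA
  f_no <- fit_twfe(p, "le")
  f_with <- fit_twfe(p, "le", controls = "gini")
  expect_equal(f_no$n_obs, nrow(p))
  expect_equal(f_with$n_obs, nrow(p) - 30)
})

test_that("constant outcome yields zero coefficients", {
  sim <- small_sim_panel(seed = 4, n = 15, gov_sw = 4, shi_sw = 1)
  p <- sim$panel
  p$flat <- 7
  f <- fit_twfe(p, "flat")
  expect_lt(max(abs(f$coefficients)), 1e-10)
})

test_that("treatment without within-variation is refused", {
  sim <- small_sim_panel(seed = 5, n = 15, gov_sw = 0, shi_sw = 0)
  p <- sim$panel
  expect_error(fit_twfe(p, "le"), "collinear with country effects")
})

test_that("cluster-robust vcov matches sandwich and scales as expected", {
  sim <- small_sim_panel(seed = 7, n = 25, gov_sw = 6, shi_sw = 2)
  p <- sim$panel
  f <- fit_twfe(p, "le", controls = "log_gdp_pc")
  lmfit <- stats::lm(le ~ SHI + GOV + log_gdp_pc + factor(year) +
                       factor(country_id), data = p)
  V <- sandwich::vcovCL(lmfit, cluster = p$country_id, type = "HC1",
                        cadjust = TRUE)
  nm <- c("SHI", "GOV", "log_gdp_pc")
  expect_equal(f$vcov[nm, nm], V[nm, nm], tolerance = 1e-8)

  # singleton clusters reduce CR1 to HC1
  set.seed(1)
  X <- cbind(1, rnorm(200))
  y <- X %*% c(1, 2) + rnorm(200)
  b <- qr.coef(qr(X), y)
  e <- as.numeric(y - X %*% b)
  Vcr <- cluster_robust_vcov(X, e, cluster = seq_len(200))
  lm2 <- stats::lm(y ~ 0 + X)
  Vhc1 <- sandwich::vcovHC(lm2, type = "HC1")
  expect_equal(unname(Vcr), unname(Vhc1), tolerance = 1e-8)

  # duplicating every cluster doubles scores: meat x4, bread x1/2 each side
  cl <- rep(1:20, each = 10)
  Xc <- cbind(1, rnorm(200)); ec <- rnorm(200)
  V1 <- cluster_robust_vcov(Xc, ec, cl)
  X2 <- rbind(Xc, Xc); e2 <- c(ec, ec); cl2 <- c(cl, cl)
  V2 <- cluster_robust_vcov(X2, e2, cl2)
  adj1 <- (20 / 19) * (199 / 198)
  adj2 <- (20 / 19) * (399 / 398)
  expect_equal(V2 / adj2, V1 / adj1, tolerance = 1e-10)

  expect_error(cluster_robust_vcov(Xc, ec, rep(1, 200)), "2 clusters")
})

test_that("random-trend model nests the main model and recovers under trends", {
  # zero-noise, zero-trend data (incl. zero common drift, which country
  # detrending would otherwise soak up): both estimators identical
  op_nl <- noiseless_params()
  op_nl$year_drift[] <- 0
  cfg <- sim_config(n_countries = 30, n_gov_switchers = 8, n_shi_switchers = 2,
                    sigma_s = 0, year_effect_sd = 0,
                    outcome_params = op_nl, seed = 31)
  p <- simulate_panel(cfg)$panel
  p$SHI <- p$SHI_true; p$GOV <- p$GOV_true
  ft <- fit_twfe(p, "le")
  fr <- fit_random_trend(p, "le")
  expect_equal(fr$coefficients[c("SHI", "GOV")],
               ft$coefficients[c("SHI", "GOV")], tolerance = 1e-6)
  # trend coefficients on trend-free data are zero
  expect_lt(max(abs(fr$trend_coefs$slope)), 1e-6)

  # switcher-correlated trends bias the plain FE fit; detrending removes it
  op <- default_outcome_params()
  op$error_sd[op$outcome == "le"] <- 0.3
  op$rho_gov[] <- 0; op$rho_shi[] <- 0
  est <- replicate(20, NA_real_); est_fe <- est
  for (r in 1:20) {
    cfg2 <- sim_config(n_countries = 60, n_gov_switchers = 15,
                       n_shi_switchers = 4, switcher_trend = 0.5,
                       outcome_params = op, seed = 400 + r)
    p2 <- simulate_panel(cfg2)$panel
    p2$SHI <- p2$SHI_true; p2$GOV <- p2$GOV_true
    est[r] <- fit_random_trend(p2, "le")$coefficients["GOV"]
    est_fe[r] <- fit_twfe(p2, "le")$coefficients["GOV"]
  }
  expect_lt(abs(mean(est)), 0.15)     # detrended: unbiased up to MC error
  expect_gt(abs(mean(est_fe)), 0.5)   # plain FE: strongly biased
})

test_that("differential-trend fit separates base effect and interactions", {
  # constant treatment effect: interactions ~ 0, mean impact ~ truth
  cfg <- sim_config(n_countries = 40, n_gov_switchers = 10,
                    n_shi_switchers = 3, sigma_s = 0, year_effect_sd = 0,
                    outcome_params = noiseless_params(), seed = 17)
  p <- simulate_panel(cfg)$panel
  p$SHI <- p$SHI_true; p$GOV <- p$GOV_true
  fd <- fit_difftrend(p, "le")
  ints <- fd$interaction_terms$GOV
  expect_gt(length(ints), 10)
  expect_lt(max(abs(fd$coefficients[ints])), 1e-6)
  mi <- mean_impact(fd, "GOV")
  expect_equal(mi$estimate, 1.341, tolerance = 1e-6)

  p0 <- p; p0$GOV <- 0
  expect_error(fit_difftrend(p0, "le"), "no treated observations")
})

test_that("mean impact follows the window-averaging formula and its oracle", {
  # synthetic fit object: rho = 1, interactions (1, 2, 3), T = 4
  fake <- structure(list(
    coefficients = c(GOV = 1, `GOV:y2` = 1, `GOV:y3` = 2, `GOV:y4` = 3),
    vcov = diag(4), se = rep(1, 4), df = 10,
    year_levels = 1:4,
    interaction_terms = list(GOV = c("GOV:y2", "GOV:y3", "GOV:y4"))),
    class = c("hfs_difftrend", "hfs_fefit"))
  mi <- mean_impact(fake, "GOV")
  expect_equal(mi$estimate, 1 + 6 / 3)

  # brute-force oracle: rho + sum(rho_t)/(T-1), reference year excluded
  rho <- fake$coefficients["GOV"]
  rhot <- fake$coefficients[fake$interaction_terms$GOV]
  expect_equal(mi$estimate, unname(rho + sum(rhot) / (length(fake$year_levels) - 1)))

  # per-year alternative averages T total effects incl. reference
  mi2 <- mean_impact(fake, "GOV", average = "per_year")
  expect_equal(mi2$estimate, unname(mean(rho + c(0, rhot))))

  # all interactions zero: mean impact equals the base coefficient
  fake0 <- fake
  fake0$coefficients[2:4] <- 0
  expect_equal(mean_impact(fake0, "GOV")$estimate, 1)
})

test_that("percent-effect translation matches printed headline values", {
  expect_equal(pct_effect(0), 0)
  expect_equal(round(pct_effect(0.117), 1), 12.4)
  expect_equal(round(pct_effect(-0.083), 1), -8.0)
  # inverse property
  for (x in c(-50, -5, 0, 5, 120))
    expect_equal(pct_effect(log(1 + x / 100)), x, tolerance = 1e-10)
})

test_that("contextual interactions estimate effect modification", {
  sim <- small_sim_panel(seed = 23, n = 40, gov_sw = 10, shi_sw = 3)
  p <- sim$panel
  fi <- fit_interaction(p, "le", cf = "informal_pct")
  expect_true(all(c("SHI", "GOV", "informal_pct", "SHI:informal_pct",
                    "GOV:informal_pct") %in% names(fi$coefficients)))

  p$flat_cf <- 1
  expect_error(fit_interaction(p, "le", cf = "flat_cf"))

  # marginal effect at cf = 0 is the base coefficient
  me0 <- marginal_effect(fi, "GOV", 0)
  expect_equal(me0$estimate, unname(fi$coefficients["GOV"]))
  expect_equal(me0$se, unname(fi$se["GOV"]))

  # delta-method SE matches a finite-difference jacobian oracle
  cfv <- 40
  me <- marginal_effect(fi, "GOV", cfv)
  g <- function(b) b[1] + b[2] * cfv
  b0 <- fi$coefficients[c("GOV", "GOV:informal_pct")]
  V <- fi$vcov[c("GOV", "GOV:informal_pct"), c("GOV", "GOV:informal_pct")]
  h <- 1e-6
  grad <- c((g(b0 + c(h, 0)) - g(b0 - c(h, 0))) / (2 * h),
            (g(b0 + c(0, h)) - g(b0 - c(0, h))) / (2 * h))
  expect_equal(me$se, sqrt(drop(t(grad) %*% V %*% grad)), tolerance = 1e-6)

  # effects interpolate linearly in the contextual factor
  m1 <- marginal_effect(fi, "GOV", 20)$estimate
  m2 <- marginal_effect(fi, "GOV", 60)$estimate
  expect_equal(marginal_effect(fi, "GOV", 40)$estimate, (m1 + m2) / 2)
  expect_true(marginal_effect(fi, "GOV", 1e6)$outside_range)
})

test_that("leads and lags shift within country and respect gaps", {
  p <- data.frame(country_id = rep(c("A", "B"), each = 4),
                  year = c(2000:2003, 2000, 2001, 2003, 2004),
                  GOV = c(0, 0, 1, 1, 0, 1, 1, 1), SHI = 0)
  a <- add_treatment_leads_lags(p, c("GOV"), leads = 1, lags = 1)
  # last observed year has no lead
  expect_true(is.na(a$GOV_lead1[a$country_id == "A" & a$year == 2003]))
  # switch at 2002: lead first equals 1 at 2001
  expect_equal(a$GOV_lead1[a$country_id == "A" & a$year == 2001], 1)
  expect_equal(a$GOV_lead1[a$country_id == "A" & a$year == 2000], 0)
  # gap year 2002 for B: no lead at 2001, no lag at 2003
  expect_true(is.na(a$GOV_lead1[a$country_id == "B" & a$year == 2001]))
  expect_true(is.na(a$GOV_lag1[a$country_id == "B" & a$year == 2003]))
  # lag of a constant series equals itself on the overlap
  p$const <- 1
  a2 <- add_treatment_leads_lags(p, "const", leads = integer(), lags = 1)
  ok <- !is.na(a2$const_lag1)
  expect_equal(a2$const_lag1[ok], p$const[ok])

  # shifts never mix countries: shuffling country block order changes nothing
  perm <- order(rev(p$country_id), p$year)
  a3 <- add_treatment_leads_lags(p[perm, ], "GOV", leads = 1)
  m1 <- a[order(a$country_id, a$year), c("country_id", "year", "GOV_lead1")]
  m3 <- a3[order(a3$country_id, a3$year), c("country_id", "year", "GOV_lead1")]
  rownames(m1) <- rownames(m3) <- NULL
  expect_equal(m1, m3)
})

test_that("event study recovers a step effect with zero pre-trend", {
  op <- default_outcome_params()
  op$error_sd[op$outcome == "le"] <- 0.05
  op$rho_gov[op$outcome == "le"] <- 2
  cfg <- sim_config(n_countries = 60, n_gov_switchers = 15,
                    n_shi_switchers = 0, outcome_params = op, seed = 51)
  sim <- simulate_panel(cfg)
  p <- sim$panel
  p$SHI <- p$SHI_true; p$GOV <- p$GOV_true
  tr <- detect_transitions_panel(p, p$regime_true)
  es <- event_study(p, "le", tr, horizon = 4)
  ref <- es[es$rel_year == -1, ]
  expect_equal(ref$estimate, 0)
  pre <- es$estimate[es$rel_year < -1]
  post <- es$estimate[es$rel_year >= 0]
  expect_lt(max(abs(pre)), 0.15)
  expect_true(all(abs(post - 2) < 0.15))

  expect_error(event_study(p, "le", tr[0, ]), "no transitions")
})

test_that("continuous-shares treatment recovers a linear dose response", {
  cfg <- sim_config(n_countries = 50, n_gov_switchers = 12,
                    n_shi_switchers = 4, seed = 61)
  sim <- simulate_panel(cfg)
  p <- sim$panel
  set.seed(61)
  p$dose <- 3 + 0.05 * p$gov_pct - 0.02 * p$shi_pct + rnorm(nrow(p), 0, 0.01)
  f <- fit_shares_treatment(p, "dose")
  expect_equal(unname(f$coefficients["gov_pct"]), 0.05, tolerance = 0.005)
  expect_equal(unname(f$coefficients["shi_pct"]), -0.02, tolerance = 0.005)

  p$gov_pct <- stats::ave(p$gov_pct, p$country_id)  # no within variation
  p$shi_pct <- stats::ave(p$shi_pct, p$country_id)
  expect_error(fit_shares_treatment(p, "dose"), "collinear")
})
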