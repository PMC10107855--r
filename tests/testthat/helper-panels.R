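# Shared fixtures, all built in code.

# tiny hand-written panel CSV (shares at the government-regime means)
toy_panel_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "country_id,year,gov_pct,shi_pct,oop_pct,other_pct,le,u5m,the_pc",
    "A,2000,62.6,2.7,21.4,13.3,70.1,20.0,500",
    "A,2001,62.6,2.7,21.4,13.3,70.4,19.5,520",
    "A,2002,62.6,2.7,21.4,13.3,70.8,19.0,540"
  ), path)
  path
}

# small simulated panel with true-regime dummies attached
small_sim_panel <- function(seed = 1, n = 40, gov_sw = 10, shi_sw = 3, ...) {
  cfg <- sim_config(n_countries = n, n_gov_switchers = gov_sw,
                    n_shi_switchers = shi_sw, seed = seed, ...)
  sim <- simulate_panel(cfg)
  p <- log_transform_outcomes(sim$panel)
  p$SHI <- p$SHI_true
  p$GOV <- p$GOV_true
  list(panel = p, truth = sim$truth, cfg = cfg)
}

# noise-free configuration: outcomes deterministic given regime path
# (covariate loadings off so fits without controls are exact too)
noiseless_params <- function() {
  op <- default_outcome_params()
  op$error_sd[] <- 1e-12
  op$country_sd[] <- 1
  op$gamma_gdp[] <- 0
  op
}

# dummy-variable OLS oracle for the within estimator
dummy_ols_coefs <- function(panel, outcome, rhs) {
  fml <- stats::as.formula(paste(
    outcome, "~", paste(c(rhs, "factor(year)", "factor(country_id)"),
                        collapse = " + ")))
  stats::coef(stats::lm(fml, data = panel))[rhs]
}
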