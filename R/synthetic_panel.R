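#' @title Synthetic country-year panel generator
#' @description Generates panels with the statistical structure the
#' estimators assume: three financing-share regimes on the simplex, planted
#' durable transitions out of OOP predominance, two-way fixed-effects
#' outcome models with known treatment effects, and configurable
#' violations (country trends, anticipation, outcome-dependent switching).
#' Ground truth is returned for recovery experiments.
#' @name synthetic_panel
NULL

# run expr with a locally seeded RNG, restoring caller state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default per-outcome generator parameters
#'
#' One row per outcome: the data-generating baseline (mean level across
#' countries; log scale for logged outcomes), the planted transition
#' effects for government- and SHI-predominant regimes (OOP is the
#' reference), the standard deviations of country effects and idiosyncratic
#' errors, the common year-effect drift per year, and the loading of log
#' GDP per capita. Baselines follow typical full-sample means for a global
#' 2000-2017 panel; planted effects default to the magnitudes a two-way FE
#' analysis of such a panel reports (e.g. +1.341 years of life expectancy
#' for a government-financing transition, +0.117 log points of THE per
#' capita for an SHI transition).
#'
#' @return data.frame with columns `outcome`, `logged`, `baseline`,
#'   `rho_gov`, `rho_shi`, `country_sd`, `error_sd`, `year_drift`,
#'   `gamma_gdp`.
#' @export
default_outcome_params <- function() {
  data.frame(
    outcome    = c("log_the_pc", "imm_idx", "le", "log_u5m", "log_mm", "cat10"),
    logged     = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    natural    = c("the_pc", "imm_idx", "le", "u5m", "mm", "cat10"),
    baseline   = c(log(1006), 85.3, 68.8, log(44.3), log(218.3), 8.1),
    rho_gov    = c(0.043, 3.804, 1.341, -0.083, -0.040, -3.256),
    rho_shi    = c(0.117, -1.486, -0.128, 0.051, 0.034, 6.467),
    country_sd = c(0.9, 8, 7, 0.9, 1.1, 3),
    error_sd   = c(0.08, 3, 1.0, 0.08, 0.10, 1.5),
    year_drift = c(0.02, 0.3, 0.25, -0.04, -0.03, -0.05),
    gamma_gdp  = c(0.8, 2, 2, -0.3, -0.3, -0.5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a 124-country, 2000-2017 panel:
#' regime centroids at the observed cluster means of (government, SHI, OOP,
#' other) shares of THE, initial regime proportions matching the observed
#' country-year mix (roughly 48\% OOP-, 32\% government-, 20\%
#' SHI-predominant), 30 countries switching from OOP to government
#' financing and 7 from OOP to SHI at uniform interior years, and additive
#' treatment effects per [default_outcome_params()].
#'
#' @param n_countries number of countries (default 124).
#' @param year_start,year_end panel window (default 2000-2017).
#' @param centroids 3 x 4 matrix of regime centroids, rows named
#'   `GOV`, `OOP`, `SHI`, columns `gov_pct`, `shi_pct`, `oop_pct`,
#'   `other_pct`; each row sums to 100.
#' @param sigma_s share noise scale on the log-ratio scale (default 0.25).
#' @param init_props initial regime proportions, named `OOP`, `GOV`, `SHI`.
#' @param n_gov_switchers,n_shi_switchers number of OOP-origin countries
#'   switching to government / SHI predominance (defaults 30 and 7).
#' @param outcome_params data.frame as [default_outcome_params()].
#' @param year_effect_sd sd of the common year shocks around the drift, as
#'   a multiple of each outcome's `error_sd` (default 0.2).
#' @param country_trend_sd sd of country-specific linear trend slopes, as a
#'   multiple of each outcome's `error_sd` per year (default 0: parallel
#'   trends hold).
#' @param switcher_trend extra linear trend slope given to switcher
#'   countries, as a multiple of each outcome's `error_sd` per year
#'   (default 0; nonzero plants a treatment-correlated differential trend,
#'   a parallel-trends violation).
#' @param anticipation_frac fraction of the treatment effect applied in the
#'   year before the switch (default 0).
#' @param endog_slope slope of the switch-year selection weight on the
#'   standardized idiosyncratic shock of `endog_outcome` in the preceding
#'   year (default 0: switch years uniform over interior years; at 0 the
#'   switch-year distribution is identical to the exogenous mode).
#' @param endog_outcome outcome driving endogenous switching (default
#'   `"le"`).
#' @param n_reverters number of government-switchers whose switch reverts
#'   to OOP after `revert_after` years (default 0: switches are absorbing).
#' @param revert_after years before reversal when `n_reverters > 0`.
#' @param confound_strength shift of switcher countries' mean log GDP per
#'   capita (default 0: controls independent of treatment).
#' @param ar_rho AR(1) coefficient for control processes (default 0.9).
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `hfs_sim_config`.
#' @export
sim_config <- function(n_countries = 124,
                       year_start = 2000, year_end = 2017,
                       centroids = default_centroids(),
                       sigma_s = 0.25,
                       init_props = c(OOP = 0.485, GOV = 0.320, SHI = 0.195),
                       n_gov_switchers = 30, n_shi_switchers = 7,
                       outcome_params = default_outcome_params(),
                       year_effect_sd = 0.2,
                       country_trend_sd = 0,
                       switcher_trend = 0,
                       anticipation_frac = 0,
                       endog_slope = 0,
                       endog_outcome = "le",
                       n_reverters = 0,
                       revert_after = 5,
                       confound_strength = 0,
                       ar_rho = 0.9,
                       seed = NULL) {
  stopifnot(n_countries >= 2, year_end > year_start,
            sigma_s >= 0, year_effect_sd >= 0, country_trend_sd >= 0,
            n_gov_switchers >= 0, n_shi_switchers >= 0, n_reverters >= 0)
  stopifnot(is.matrix(centroids), nrow(centroids) == 3, ncol(centroids) == 4)
  if (any(centroids < 0))
    stop("centroid components must be nonnegative")
  if (any(abs(rowSums(centroids) - 100) > 1e-9))
    stop("each centroid must sum to 100")
  init_props <- init_props / sum(init_props)
  n_oop <- round(n_countries * init_props[["OOP"]])
  if (n_gov_switchers + n_shi_switchers > n_oop)
    stop(sprintf("infeasible switcher counts: %d + %d switchers but only %d initial-OOP countries",
                 n_gov_switchers, n_shi_switchers, n_oop))
  if (n_reverters > n_gov_switchers)
    stop("n_reverters cannot exceed n_gov_switchers")
  structure(list(
    n_countries = n_countries, year_start = year_start, year_end = year_end,
    centroids = centroids, sigma_s = sigma_s, init_props = init_props,
    n_gov_switchers = n_gov_switchers, n_shi_switchers = n_shi_switchers,
    outcome_params = outcome_params, year_effect_sd = year_effect_sd,
    country_trend_sd = country_trend_sd, switcher_trend = switcher_trend,
    anticipation_frac = anticipation_frac, endog_slope = endog_slope,
    endog_outcome = endog_outcome, n_reverters = n_reverters,
    revert_after = revert_after, confound_strength = confound_strength,
    ar_rho = ar_rho, seed = seed
  ), class = "hfs_sim_config")
}

#' Default regime centroids (shares of THE, percent)
#'
#' Cluster means of government, SHI, OOP and residual ("other") financing
#' shares for government-, OOP- and SHI-predominant country-years in a
#' global 2000-2017 panel.
#'
#' @return 3 x 4 matrix, rows `GOV`, `OOP`, `SHI`.
#' @export
default_centroids <- function() {
  m <- rbind(GOV = c(62.6, 2.7, 21.4, 13.3),
             OOP = c(28.6, 7.3, 51.6, 12.5),
             SHI = c(11.0, 59.3, 23.6, 6.1))
  colnames(m) <- c("gov_pct", "shi_pct", "oop_pct", "other_pct")
  m
}

#' Draw one compositional share vector around a regime centroid
#'
#' Additive-logistic-normal draw on the 4-part simplex:
#' softmax(log(centroid/100) + N(0, sigma_s^2) per coordinate) x 100.
#' Components sum to 100 exactly. Zero centroid components are floored at
#' 1e-6 before the log so degenerate centroids remain usable.
#'
#' @param centroid 4-vector of percentages summing to 100.
#' @param sigma_s log-ratio noise scale, >= 0. At 0 the centroid is
#'   returned exactly (up to the floor).
#' @param n number of draws.
#' @return n x 4 matrix of percentages, rows summing to 100.
#' @export
simulate_shares <- function(centroid, sigma_s, n = 1) {
  stopifnot(length(centroid) == 4, all(centroid >= 0), sigma_s >= 0, n >= 1)
  p <- pmax(centroid / 100, 1e-6)
  lp <- matrix(log(p), n, 4, byrow = TRUE)
  if (sigma_s > 0)
    lp <- lp + matrix(stats::rnorm(n * 4, 0, sigma_s), n, 4)
  e <- exp(lp - apply(lp, 1, max))
  out <- 100 * e / rowSums(e)
  colnames(out) <- names(centroid)
  out
}

#' Assign regime paths with planted transitions
#'
#' Initial regimes are assigned by the configured proportions; the
#' configured numbers of OOP-origin countries receive absorbing switches to
#' government or SHI predominance at switch years drawn uniformly over the
#' interior years of the window. In endogenous mode (`endog_slope != 0`)
#' each switcher's switch year is instead drawn with selection weights
#' proportional to `exp(endog_slope * z)`, where z is the standardized
#' idiosyncratic shock of the configured outcome in the year preceding the
#' candidate switch year; at slope 0 this reduces exactly to the uniform
#' draw. Optionally the first `n_reverters` government switchers revert to
#' OOP after `revert_after` years (reversible-treatment variant).
#'
#' @param cfg `hfs_sim_config`.
#' @param eps_endog optional n_countries x T matrix of standardized shocks
#'   used by the endogenous mode (supplied by [simulate_panel()]).
#' @return list with `regimes` (n x T character matrix of labels),
#'   `switch_year`, `from`, `to` per country (NA where no switch).
#' @export
assign_transition_schedule <- function(cfg, eps_endog = NULL) {
  years <- cfg$year_start:cfg$year_end
  T <- length(years)
  n <- cfg$n_countries
  n_oop <- round(n * cfg$init_props[["OOP"]])
  n_gov <- round(n * cfg$init_props[["GOV"]])
  n_shi <- n - n_oop - n_gov
  init <- c(rep("OOP", n_oop), rep("GOV", n_gov), rep("SHI", n_shi))

  regimes <- matrix(rep(init, T), n, T)
  switch_year <- rep(NA_integer_, n)
  to <- rep(NA_character_, n)

  ns <- cfg$n_gov_switchers + cfg$n_shi_switchers
  if (ns > 0) {
    switchers <- sample.int(n_oop, ns)
    dest <- c(rep("GOV", cfg$n_gov_switchers), rep("SHI", cfg$n_shi_switchers))
    interior <- years[-c(1, T)]
    for (j in seq_along(switchers)) {
      i <- switchers[j]
      if (!is.null(eps_endog) && cfg$endog_slope != 0) {
        # weight on shock of the year preceding each candidate switch year
        z <- eps_endog[i, match(interior, years) - 1]
        w <- exp(cfg$endog_slope * z)
        s <- interior[sample.int(length(interior), 1, prob = w / sum(w))]
      } else {
        s <- interior[sample.int(length(interior), 1)]
      }
      switch_year[i] <- s
      to[i] <- dest[j]
      regimes[i, years >= s] <- dest[j]
    }
    if (cfg$n_reverters > 0) {
      gov_sw <- switchers[dest == "GOV"]
      rev <- gov_sw[seq_len(cfg$n_reverters)]
      for (i in rev) {
        back <- switch_year[i] + cfg$revert_after
        if (back <= cfg$year_end) regimes[i, years >= back] <- "OOP"
      }
    }
  }
  list(regimes = regimes, switch_year = switch_year,
       from = ifelse(is.na(to), NA_character_, "OOP"), to = to)
}

#' Simulate a country-year panel with known ground truth
#'
#' Builds a balanced panel of `n_countries` x T rows. Shares are
#' logistic-normal draws around the country's current regime centroid;
#' each outcome follows
#' \deqn{y_{it} = \alpha_i + \tau_t + \rho_1 SHI_{it} + \rho_2 GOV_{it} +
#'   \gamma x_{it} + c_i t + \varepsilon_{it}}
#' with the planted regime dummies, country and year effects, optional
#' country trends and the configured violations. Logged outcomes are
#' generated on the log scale and exponentiated into their natural columns
#' so that [log_transform_outcomes()] recovers the generating scale.
#'
#' @param cfg `hfs_sim_config`.
#' @return list with `panel` (validated `hfs_panel`) and `truth`
#'   (`hfs_sim_truth`: regime paths, switch years, true effects, realized
#'   country/year effects and trends).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "hfs_sim_config"))
  with_local_seed(cfg$seed, {
    years <- cfg$year_start:cfg$year_end
    T <- length(years)
    n <- cfg$n_countries
    op <- cfg$outcome_params
    ids <- sprintf("C%03d", seq_len(n))

    # shocks drawn first: the endogenous switching mode selects switch
    # years on the lagged standardized shock of one outcome
    eps <- lapply(seq_len(nrow(op)), function(k)
      matrix(stats::rnorm(n * T, 0, op$error_sd[k]), n, T))
    names(eps) <- op$outcome

    endog_name <- cfg$endog_outcome
    if (!endog_name %in% op$outcome)
      endog_name <- op$outcome[match(cfg$endog_outcome, op$natural)]
    z_endog <- eps[[endog_name]] / op$error_sd[op$outcome == endog_name]

    sched <- assign_transition_schedule(cfg, eps_endog = z_endog)
    regimes <- sched$regimes

    # shares around the current regime centroid, row by regime
    lab_vec <- as.vector(regimes)              # country-major? matrix is n x T
    long_country <- rep(ids, times = T)
    long_year <- rep(years, each = n)
    shares <- matrix(NA_real_, n * T, 4)
    for (r in rownames(cfg$centroids)) {
      idx <- which(lab_vec == r)
      if (length(idx))
        shares[idx, ] <- simulate_shares(cfg$centroids[r, ], cfg$sigma_s,
                                         n = length(idx))
    }
    colnames(shares) <- colnames(cfg$centroids)

    shi_d <- as.numeric(lab_vec == "SHI")
    gov_d <- as.numeric(lab_vec == "GOV")

    # controls: AR(1) around country means; log GDP may load on outcomes
    is_switcher <- !is.na(sched$switch_year)
    ar1 <- function(mu_i, innov_sd, trend = 0) {
      x <- matrix(0, n, T)
      x[, 1] <- mu_i + stats::rnorm(n, 0, innov_sd / sqrt(1 - cfg$ar_rho^2))
      for (t in 2:T)
        x[, t] <- mu_i + cfg$ar_rho * (x[, t - 1] - mu_i) +
          stats::rnorm(n, 0, innov_sd)
      x + outer(rep(1, n), (seq_len(T) - 1)) * trend
    }
    mu_gdp <- stats::rnorm(n, log(15394), 1.0) +
      cfg$confound_strength * is_switcher
    log_gdp <- ar1(mu_gdp, 0.05, trend = 0.02)
    controls <- list(
      log_gdp_pc  = log_gdp,
      educ_enroll = pmax(ar1(stats::rnorm(n, 102, 8), 1.5), 0),
      water_pct   = pmin(pmax(ar1(stats::rnorm(n, 83, 10), 1.0, 0.2), 0), 100),
      urban_pct   = pmin(pmax(ar1(stats::rnorm(n, 56, 15), 0.5, 0.3), 0), 100),
      gini        = pmax(ar1(stats::rnorm(n, 38, 6), 0.5), 10),
      pop65_pct   = pmin(pmax(ar1(stats::rnorm(n, 7.7, 4), 0.2, 0.05), 0), 100),
      pop14_pct   = pmin(pmax(ar1(stats::rnorm(n, 29.6, 8), 0.3, -0.1), 0), 100),
      gov_eff     = ar1(stats::rnorm(n, -0.05, 0.9), 0.08),
      corr_ctrl   = ar1(stats::rnorm(n, -0.10, 0.9), 0.08)
    )
    regime_informal <- c(GOV = 48.4, OOP = 65.95, SHI = 32.68)
    informal <- matrix(regime_informal[regimes], n, T) +
      ar1(stats::rnorm(n, 0, 6), 1.0)
    informal <- pmin(pmax(informal, 0), 100)
    payroll <- pmin(pmax(matrix(c(GOV = 2.1, OOP = 6.3, SHI = 42.7)[regimes],
                                n, T) + ar1(stats::rnorm(n, 0, 2), 0.5), 0), 100)
    gge <- pmin(pmax(matrix(c(GOV = 34.5, OOP = 23.9, SHI = 39.4)[regimes],
                            n, T) + ar1(stats::rnorm(n, 0, 4), 0.8), 0), 100)

    gdp_dev <- log_gdp - log(15394)

    tt <- seq_len(T) - 1
    outcomes <- list()
    alpha <- matrix(NA_real_, n, nrow(op), dimnames = list(ids, op$outcome))
    tau <- matrix(NA_real_, T, nrow(op), dimnames = list(years, op$outcome))
    trends <- matrix(0, n, nrow(op), dimnames = list(ids, op$outcome))
    for (k in seq_len(nrow(op))) {
      o <- op[k, ]
      a_i <- stats::rnorm(n, o$baseline, o$country_sd)
      t_t <- o$year_drift * tt +
        stats::rnorm(T, 0, cfg$year_effect_sd * o$error_sd)
      t_t[1] <- 0
      c_i <- stats::rnorm(n, 0, cfg$country_trend_sd * o$error_sd) +
        cfg$switcher_trend * o$error_sd * is_switcher
      alpha[, k] <- a_i; tau[, k] <- t_t; trends[, k] <- c_i

      y <- matrix(a_i, n, T) + matrix(t_t, n, T, byrow = TRUE) +
        outer(c_i, tt) + o$gamma_gdp * gdp_dev + eps[[o$outcome]]
      y <- y + o$rho_shi * matrix(shi_d, n, T) +
        o$rho_gov * matrix(gov_d, n, T)
      if (cfg$anticipation_frac != 0) {
        for (i in which(is_switcher)) {
          s <- sched$switch_year[i]
          if (s - 1 >= cfg$year_start) {
            rho <- if (sched$to[i] == "GOV") o$rho_gov else o$rho_shi
            y[i, match(s - 1, years)] <- y[i, match(s - 1, years)] +
              cfg$anticipation_frac * rho
          }
        }
      }
      outcomes[[o$outcome]] <- y
    }

    panel <- data.frame(country_id = long_country, year = long_year,
                        stringsAsFactors = FALSE)
    panel <- cbind(panel, as.data.frame(shares))
    nat <- function(k) {
      y <- as.vector(outcomes[[op$outcome[k]]])
      if (op$logged[k]) exp(y) else y
    }
    for (k in seq_len(nrow(op))) panel[[op$natural[k]]] <- nat(k)
    panel$imm_idx <- pmin(pmax(panel$imm_idx, 0), 100)
    panel$cat10 <- pmin(pmax(panel$cat10, 0), 100)
    panel$le <- pmax(panel$le, 20)
    for (nm in names(controls)) panel[[nm]] <- as.vector(controls[[nm]])
    panel$informal_pct <- as.vector(informal)
    panel$payroll_rev_pct <- as.vector(payroll)
    panel$gge_gdp_pct <- as.vector(gge)
    panel$regime_true <- lab_vec
    panel$SHI_true <- shi_d
    panel$GOV_true <- gov_d

    panel <- validate_panel(panel)

    truth <- structure(list(
      country_id = ids, years = years,
      regimes = regimes, switch_year = sched$switch_year,
      from = sched$from, to = sched$to,
      effects = op[, c("outcome", "rho_gov", "rho_shi")],
      country_effects = alpha, year_effects = tau, country_trends = trends,
      config = cfg
    ), class = "hfs_sim_truth")

    list(panel = panel, truth = truth)
  })
}
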