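#' @title Two-way fixed-effects estimators with cluster-robust inference
#' @description Panel difference-in-differences regressions of outcomes on
#' financing-system dummies: the main two-way fixed-effects (country and
#' year) specification, a random-trend variant with country-specific linear
#' trends, a differential-trend variant with treatment-by-year
#' interactions, contextual-factor interactions, leads/lags, event-study
#' curves and continuous-shares treatments. Country effects (and country
#' trends) are absorbed by within-transformation; year effects enter as
#' dummies. Inference uses a CR1 cluster-robust sandwich with t(G-1)
#' reference, clusters = countries.
#' @name fe_estimators
NULL

#' Cluster-robust (CR1) covariance for a linear regression
#'
#' Sandwich estimator \eqn{c (X'X)^{-1} (\sum_g X_g' e_g e_g' X_g)
#' (X'X)^{-1}} with the CR1 small-sample factor
#' \eqn{c = [G/(G-1)] [(N-1)/(N-K)]}. With every observation its own
#' cluster this reduces to the HC1 heteroskedasticity-robust covariance.
#' Coefficient tests downstream use a t reference with G-1 degrees of
#' freedom.
#'
#' @param X design matrix (full column rank, N x p).
#' @param resid residual vector, length N.
#' @param cluster cluster id vector, length N (G >= 2 distinct values).
#' @param K model degrees of freedom consumed, including absorbed fixed
#'   effects; defaults to `ncol(X)`.
#' @return p x p covariance matrix.
#' @export
cluster_robust_vcov <- function(X, resid, cluster, K = ncol(X)) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(length(resid) == N, length(cluster) == N)
  G <- length(unique(cluster))
  if (G < 2) stop("cluster-robust covariance needs at least 2 clusters")
  if (N <= K) stop("more parameters than observations (N <= K)")
  bread <- chol2inv(chol(crossprod(X)))
  scores <- rowsum(X * resid, cluster)
  meat <- crossprod(scores)
  c_adj <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- c_adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# year-dummy matrix, first observed year as reference
year_dummies <- function(year) {
  lev <- sort(unique(year))
  if (length(lev) < 2) return(list(X = NULL, terms = character(), levels = lev))
  D <- sapply(lev[-1], function(y) as.numeric(year == y))
  colnames(D) <- paste0("y", lev[-1])
  list(X = D, terms = colnames(D), levels = lev)
}

# demean (or detrend) columns within country
absorb_within <- function(M, country, trend = FALSE, tt = NULL) {
  M <- as.matrix(M)
  if (!trend) {
    cm <- rowsum(M, country)
    cnt <- as.vector(rowsum(rep(1, length(country)), country))
    cm <- cm / cnt
    M - cm[match(country, rownames(cm)), , drop = FALSE]
  } else {
    out <- M
    for (g in split(seq_along(country), country)) {
      Z <- cbind(1, tt[g])
      out[g, ] <- M[g, , drop = FALSE] -
        Z %*% qr.solve(Z, M[g, , drop = FALSE])
    }
    out
  }
}

# greedy full-rank column selection (drop order: by column position)
select_columns <- function(X, tol = 1e-8) {
  qrx <- qr(X, tol = tol)
  if (qrx$rank == ncol(X)) return(list(keep = seq_len(ncol(X)), dropped = character()))
  keep <- integer()
  for (j in seq_len(ncol(X))) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE], tol = tol)$rank == length(cand))
      keep <- cand
  }
  list(keep = keep, dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

# shared fitting engine for all specifications
fit_core <- function(panel, outcome, rhs, controls = character(),
                     trend = FALSE, model_name = "twfe",
                     treatments = character(), min_years = if (trend) 3 else 2) {
  cols <- unique(c("country_id", "year", outcome, rhs, controls))
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(panel)[, cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  # countries need enough observations for the absorbed effects
  cnt <- table(d$country_id)
  d <- d[d$country_id %in% names(cnt)[cnt >= min_years], , drop = FALSE]
  if (nrow(d) == 0) stop("no usable observations after listwise deletion")
  G <- length(unique(d$country_id))
  if (G < 2) stop("need at least 2 countries with usable data")

  yd <- year_dummies(d$year)
  Xr <- as.matrix(d[, c(rhs, controls), drop = FALSE])
  storage.mode(Xr) <- "double"
  X <- if (is.null(yd$X)) Xr else cbind(Xr, yd$X)
  y <- as.numeric(d[[outcome]])

  tt <- d$year - min(d$year)
  Xw <- absorb_within(X, d$country_id, trend = trend, tt = tt)
  yw <- as.numeric(absorb_within(matrix(y), d$country_id, trend = trend, tt = tt))

  for (tr in intersect(treatments, colnames(Xw))) {
    if (max(abs(Xw[, tr])) < 1e-10)
      stop("treatment ", tr, " is collinear with country effects ",
           "(no within-country variation)")
  }

  sel <- select_columns(Xw)
  if (!length(sel$keep)) stop("design is entirely collinear with fixed effects")
  Xk <- Xw[, sel$keep, drop = FALSE]

  qrx <- qr(Xk)
  beta <- qr.coef(qrx, yw)
  e <- yw - as.vector(Xk %*% beta)

  N <- nrow(Xk)
  K <- ncol(Xk) + G * (1 + trend)
  if (N > K) {
    V <- cluster_robust_vcov(Xk, e, d$country_id, K = K)
  } else {
    # saturated design: coefficients exist but no residual df for SEs
    V <- matrix(NA_real_, ncol(Xk), ncol(Xk),
                dimnames = list(colnames(Xk), colnames(Xk)))
  }
  se <- sqrt(diag(V))
  df <- G - 1
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)

  sst <- sum(yw^2)
  ssr <- sum(e^2)
  r2w <- if (sst > 0) 1 - ssr / sst else NA_real_
  r2adj <- if (sst > 0 && N > K) 1 - (1 - r2w) * (N - 1) / (N - K) else NA_real_

  structure(list(
    model = model_name, outcome = outcome,
    coefficients = stats::setNames(as.numeric(beta), colnames(Xk)),
    vcov = V, se = stats::setNames(se, colnames(Xk)),
    tstat = tstat, p_value = pval, df = df,
    n_obs = N, n_countries = G, K = K,
    r2_within = r2w, r2_adj = r2adj,
    residuals = data.frame(country_id = d$country_id, year = d$year,
                           resid = e),
    dropped = sel$dropped,
    treatments = treatments, controls = controls,
    year_terms = intersect(yd$terms, colnames(Xk)),
    year_levels = yd$levels,
    data_used = d
  ), class = "hfs_fefit")
}

#' @export
print.hfs_fefit <- function(x, ...) {
  cat(sprintf("<%s fit> outcome = %s, N = %d, countries = %d, within R2 = %.3f\n",
              x$model, x$outcome, x$n_obs, x$n_countries, x$r2_within))
  show <- setdiff(names(x$coefficients), x$year_terms)
  tab <- data.frame(estimate = x$coefficients[show], se = x$se[show],
                    t = x$tstat[show], p = x$p_value[show])
  print(round(utils::head(tab, 12), 4))
  if (length(x$dropped)) cat("dropped (collinear):",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy coefficient table of a fit
#' @param fit an `hfs_fefit`.
#' @param terms optional subset of coefficient names.
#' @return data.frame `name`, `estimate`, `se`, `statistic`, `p_value`.
#' @export
coef_table <- function(fit, terms = NULL) {
  nm <- if (is.null(terms)) names(fit$coefficients) else terms
  data.frame(name = nm, estimate = unname(fit$coefficients[nm]),
             se = unname(fit$se[nm]), statistic = unname(fit$tstat[nm]),
             p_value = unname(fit$p_value[nm]), stringsAsFactors = FALSE)
}

#' Main two-way fixed-effects specification
#'
#' \deqn{y_{it} = \alpha + \rho_1 SHI_{it} + \rho_2 GOV_{it} +
#'   \gamma' x_{it} + \tau_t + c_i + \varepsilon_{it}}
#' Country effects are absorbed by within-demeaning, year effects enter as
#' dummies (first observed year as reference); the coefficients equal the
#' full dummy-variable OLS. Listwise deletion per model. SEs are CR1
#' cluster-robust at the country level, tests use t(G-1).
#'
#' @param panel panel data.frame containing the treatment dummy columns
#'   (see [labels_to_dummies()]), the outcome and any controls.
#' @param outcome outcome column name.
#' @param treatments treatment dummy columns (default `c("SHI", "GOV")`).
#' @param controls control columns (default none).
#' @return `hfs_fefit`.
#' @export
fit_twfe <- function(panel, outcome, treatments = c("SHI", "GOV"),
                     controls = character()) {
  fit_core(panel, outcome, rhs = treatments, controls = controls,
           trend = FALSE, model_name = "twfe", treatments = treatments)
}

#' Random-trend specification (country-specific linear trends)
#'
#' The main specification augmented with a linear trend per country,
#' absorbed jointly with the country effect by within-country detrending
#' (partitioned regression); year effects remain as dummies. Countries
#' contribute only if observed in at least 3 years.
#'
#' @inheritParams fit_twfe
#' @return `hfs_fefit` with subclass `hfs_trendfit` and an extra
#'   `trend_coefs` data.frame (fitted slope per country).
#' @export
fit_random_trend <- function(panel, outcome, treatments = c("SHI", "GOV"),
                             controls = character()) {
  fit <- fit_core(panel, outcome, rhs = treatments, controls = controls,
                  trend = TRUE, model_name = "random_trend",
                  treatments = treatments)
  d <- fit$data_used
  yd <- year_dummies(d$year)
  X <- cbind(as.matrix(d[, c(treatments, controls), drop = FALSE]),
             yd$X)[, names(fit$coefficients), drop = FALSE]
  part <- as.numeric(d[[fit$outcome]]) - as.vector(X %*% fit$coefficients)
  tt <- d$year - min(d$year)
  sl <- vapply(split(seq_len(nrow(d)), d$country_id), function(g) {
    stats::coef(stats::lm.fit(cbind(1, tt[g]), part[g]))[2]
  }, numeric(1))
  fit$trend_coefs <- data.frame(country_id = names(sl), slope = unname(sl),
                                stringsAsFactors = FALSE)
  class(fit) <- c("hfs_trendfit", class(fit))
  fit
}

#' Differential-trend specification (treatment x year interactions)
#'
#' Adds to the main specification a full set of interactions between each
#' treatment dummy and the year dummies (first observed year excluded as
#' reference), allowing each treatment group its own nonlinear time
#' profile. The joint cluster-robust covariance of the base effects, the
#' interactions and the year effects is retained for the nonlinear
#' parallel-trend restriction test and the mean-impact summary. Empty or
#' collinear treatment-year cells are dropped and recorded in `dropped`.
#'
#' @inheritParams fit_twfe
#' @return `hfs_fefit` with subclass `hfs_difftrend` and
#'   `interaction_terms` (named list, kept interaction coefficients per
#'   treatment).
#' @export
fit_difftrend <- function(panel, outcome, treatments = c("SHI", "GOV"),
                          controls = character()) {
  for (tr in treatments) {
    if (!tr %in% names(panel)) stop("missing treatment column: ", tr)
    if (sum(panel[[tr]], na.rm = TRUE) == 0)
      stop("no treated observations for ", tr)
  }
  # build interactions on a working copy; year set from usable rows
  cols <- unique(c("country_id", "year", outcome, treatments, controls))
  d <- as.data.frame(panel)[, cols]
  ok <- stats::complete.cases(d)
  lev <- sort(unique(d$year[ok]))
  work <- as.data.frame(panel)
  inter <- list()
  for (tr in treatments) {
    nms <- character()
    for (y in lev[-1]) {
      nm <- paste0(tr, ":y", y)
      work[[nm]] <- work[[tr]] * as.numeric(work$year == y)
      nms <- c(nms, nm)
    }
    inter[[tr]] <- nms
  }
  rhs <- c(treatments, unlist(inter))
  fit <- fit_core(work, outcome, rhs = rhs, controls = controls,
                  trend = FALSE, model_name = "difftrend",
                  treatments = treatments)
  fit$interaction_terms <- lapply(inter, intersect, names(fit$coefficients))
  class(fit) <- c("hfs_difftrend", class(fit))
  fit
}

#' Mean impact of a transition in the differential-trend model
#'
#' The average effect over the panel window:
#' \eqn{\rho + (\sum_{t=2}^{T} \rho_t) / (T - 1)}, where \eqn{\rho} is the
#' base treatment coefficient and \eqn{\rho_t} the treatment-by-year
#' interactions (zero in the reference year, which is excluded from the
#' sum but counted in \eqn{T}). The SE comes from the linear form a'Va on
#' the joint cluster-robust covariance. `average = "per_year"` instead
#' averages the T per-year total effects \eqn{\rho + \rho_t} (reference
#' year contributing \eqn{\rho}); the divisor-(T-1) form is the default.
#'
#' @param fit `hfs_difftrend`.
#' @param which treatment name (`"SHI"` or `"GOV"`).
#' @param average `"window"` (default, divide the interaction sum by T-1)
#'   or `"per_year"`.
#' @return list: `estimate`, `se`, `statistic`, `p_value`, `df`.
#' @export
mean_impact <- function(fit, which, average = c("window", "per_year")) {
  average <- match.arg(average)
  stopifnot(inherits(fit, "hfs_difftrend"))
  if (!which %in% names(fit$coefficients))
    stop("no base coefficient for ", which)
  ints <- fit$interaction_terms[[which]]
  if (is.null(ints) || !length(ints))
    stop("fit has no interaction terms for ", which)
  T <- length(fit$year_levels)
  a <- stats::setNames(numeric(length(fit$coefficients)),
                       names(fit$coefficients))
  rho <- fit$coefficients[[which]]
  rhot <- fit$coefficients[ints]
  if (average == "window") {
    a[which] <- 1
    a[ints] <- 1 / (T - 1)
    est <- rho + sum(rhot) / (T - 1)
  } else {
    a[which] <- 1
    a[ints] <- 1 / T
    est <- rho + sum(rhot) / T
  }
  se <- sqrt(as.numeric(t(a) %*% fit$vcov %*% a))
  stat <- est / se
  list(estimate = est, se = se, statistic = stat,
       p_value = 2 * stats::pt(-abs(stat), fit$df), df = fit$df)
}

#' Percent-change interpretation of a log-outcome coefficient
#'
#' For outcomes entering the model in natural logs, a treatment coefficient
#' \eqn{\rho} translates to a percent change \eqn{(e^\rho - 1) \times 100}.
#' Report to one decimal.
#'
#' @param rho coefficient on a logged outcome.
#' @return percent change (numeric, full precision).
#' @export
pct_effect <- function(rho) (exp(rho) - 1) * 100

#' Contextual-factor interaction specification
#'
#' Adds a contextual factor and its interactions with the treatment
#' dummies to the main specification:
#' \deqn{y = \beta_1 SHI \times CF + \beta_2 GOV \times CF + CF + SHI +
#'   GOV + \gamma' x + \tau_t + c_i + \varepsilon}
#'
#' @inheritParams fit_twfe
#' @param cf contextual-factor column name.
#' @return `hfs_fefit` with subclass `hfs_interaction`; interaction
#'   coefficients are named `<treatment>:<cf>`. Stores the observed cf
#'   range for [marginal_effect()].
#' @export
fit_interaction <- function(panel, outcome, cf,
                            treatments = c("SHI", "GOV"),
                            controls = character()) {
  if (!cf %in% names(panel)) stop("missing contextual factor column: ", cf)
  work <- as.data.frame(panel)
  nms <- paste0(treatments, ":", cf)
  for (j in seq_along(treatments))
    work[[nms[j]]] <- work[[treatments[j]]] * work[[cf]]
  fit <- fit_core(work, outcome, rhs = c(treatments, cf, nms),
                  controls = controls, trend = FALSE,
                  model_name = "interaction", treatments = treatments)
  if (stats::sd(fit$data_used[[cf]]) < 1e-12)
    stop("contextual factor ", cf, " is constant in the estimation sample")
  fit$cf <- cf
  fit$cf_range <- range(fit$data_used[[cf]])
  fit$cf_terms <- stats::setNames(nms, treatments)
  class(fit) <- c("hfs_interaction", class(fit))
  fit
}

#' Marginal effect of a transition at a contextual-factor value
#'
#' From an interaction fit, the effect of `treatment` at `cf_value` is
#' \eqn{\rho + \beta \cdot cf} with delta-method (here exact linear-form)
#' SE \eqn{\sqrt{v_{\rho\rho} + cf^2 v_{\beta\beta} + 2 cf v_{\rho\beta}}}.
#'
#' @param fit `hfs_interaction`.
#' @param treatment treatment name.
#' @param cf_value value of the contextual factor.
#' @return list: `estimate`, `se`, `statistic`, `p_value`, `df`,
#'   `outside_range` (TRUE if `cf_value` outside the observed range).
#' @export
marginal_effect <- function(fit, treatment, cf_value) {
  stopifnot(inherits(fit, "hfs_interaction"))
  b_nm <- fit$cf_terms[[treatment]]
  if (is.null(b_nm) || !treatment %in% names(fit$coefficients) ||
      !b_nm %in% names(fit$coefficients))
    stop("fit lacks coefficients for treatment ", treatment)
  rho <- fit$coefficients[[treatment]]
  bet <- fit$coefficients[[b_nm]]
  V <- fit$vcov[c(treatment, b_nm), c(treatment, b_nm)]
  est <- rho + bet * cf_value
  se <- sqrt(V[1, 1] + cf_value^2 * V[2, 2] + 2 * cf_value * V[1, 2])
  stat <- est / se
  list(estimate = est, se = se, statistic = stat,
       p_value = 2 * stats::pt(-abs(stat), fit$df), df = fit$df,
       outside_range = cf_value < fit$cf_range[1] | cf_value > fit$cf_range[2])
}

#' Add within-country leads and lags of treatment columns
#'
#' Shifted columns `<name>_lead<k>` / `<name>_lag<k>`. Shifts never cross
#' country boundaries, and require the shifted year to be present (a gap
#' yields NA); edge years are NA and drop out at fit time.
#'
#' @param panel panel data.frame.
#' @param treatments columns to shift.
#' @param leads,lags integer vectors of horizons (default `1` and none).
#' @return panel with shifted columns appended.
#' @export
add_treatment_leads_lags <- function(panel, treatments = c("SHI", "GOV"),
                                     leads = 1, lags = integer()) {
  d <- as.data.frame(panel)
  shift_one <- function(v, year, k) v[match(year + k, year)]
  for (tr in treatments) {
    for (k in leads) {
      nm <- paste0(tr, "_lead", k)
      d[[nm]] <- unsplit(lapply(split(seq_len(nrow(d)), d$country_id),
                                function(ix) shift_one(d[[tr]][ix], d$year[ix], k)),
                         d$country_id)
    }
    for (k in lags) {
      nm <- paste0(tr, "_lag", k)
      d[[nm]] <- unsplit(lapply(split(seq_len(nrow(d)), d$country_id),
                                function(ix) shift_one(d[[tr]][ix], d$year[ix], -k)),
                         d$country_id)
    }
  }
  d
}

#' Event-study curve around financing transitions
#'
#' Fixed-effects regression on relative-time dummies around each country's
#' single transition (reference: the year before the switch), endpoints
#' binned at the horizon. Countries with multiple transitions are excluded
#' from this analysis; countries with none serve as controls.
#'
#' @param panel panel data.frame.
#' @param outcome outcome column.
#' @param transitions data.frame from [detect_transitions_panel()].
#' @param horizon bin limit H in years (default 5).
#' @param controls control columns.
#' @return data.frame `rel_year`, `estimate`, `se`, `ci_lo`, `ci_hi` with
#'   the reference year fixed at 0; attribute `fit` holds the underlying
#'   `hfs_fefit`.
#' @export
event_study <- function(panel, outcome, transitions, horizon = 5,
                        controls = character()) {
  if (is.null(transitions) || nrow(transitions) == 0)
    stop("no transitions supplied")
  multi <- names(which(table(transitions$country_id) > 1))
  tr1 <- transitions[!transitions$country_id %in% multi, , drop = FALSE]
  if (nrow(tr1) == 0) stop("no single-transition countries available")
  work <- as.data.frame(panel)
  sw <- stats::setNames(tr1$switch_year, tr1$country_id)
  rel <- work$year - sw[work$country_id]   # NA for untreated countries
  rel <- pmin(pmax(rel, -horizon), horizon)
  bins <- setdiff(seq(-horizon, horizon), -1)
  nms <- paste0("rel_", ifelse(bins < 0, paste0("m", -bins), paste0("p", bins)))
  for (j in seq_along(bins))
    work[[nms[j]]] <- as.numeric(!is.na(rel) & rel == bins[j])
  fit <- fit_core(work, outcome, rhs = nms, controls = controls,
                  trend = FALSE, model_name = "event_study",
                  treatments = character())
  kept <- intersect(nms, names(fit$coefficients))
  out <- data.frame(rel_year = c(bins[bins < 0], -1, bins[bins >= 0]),
                    estimate = 0, se = NA_real_)
  rn <- c(nms[bins < 0], "rel_m1", nms[bins >= 0])
  for (i in seq_len(nrow(out))) {
    nm <- rn[i]
    if (nm %in% kept) {
      out$estimate[i] <- fit$coefficients[[nm]]
      out$se[i] <- fit$se[[nm]]
    }
  }
  crit <- stats::qt(0.975, fit$df)
  out$ci_lo <- out$estimate - crit * out$se
  out$ci_hi <- out$estimate + crit * out$se
  attr(out, "fit") <- fit
  out
}

#' Continuous financing shares as treatments
#'
#' The main specification with government and SHI shares of THE as
#' continuous treatments instead of regime dummies; the OOP share is
#' omitted (shares are collinear: they sum to near 100 with the residual
#' share).
#'
#' @inheritParams fit_twfe
#' @return `hfs_fefit` with treatments `gov_pct`, `shi_pct`.
#' @export
fit_shares_treatment <- function(panel, outcome, controls = character()) {
  fit_core(panel, outcome, rhs = c("gov_pct", "shi_pct"),
           controls = controls, trend = FALSE, model_name = "shares",
           treatments = c("gov_pct", "shi_pct"))
}
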