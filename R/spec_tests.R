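#' @title Specification tests for the fixed-effects DiD design
#' @description The test battery around the main estimator: a Clogg-style
#' Z-test comparing a coefficient across models with and without country
#' trends, a delta-method Wald test of the nonlinear parallel-trend ratio
#' restriction in the differential-trend model, lead-based
#' reverse-causality tests, the government-vs-SHI coefficient difference
#' test, and a Goodman-Bacon timing-group decomposition for the
#' absorbing-switch sub-design.
#' @name spec_tests
NULL

test_result <- function(test, statistic, distribution, p_value,
                        components = NULL, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = statistic,
                 distribution = distribution, p_value = p_value,
                 components = components, note = note),
            class = "hfs_test_result")
}

#' @export
print.hfs_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g (%s), p = %.4g\n",
              x$test, x$statistic, x$distribution, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Clogg test: same coefficient across nested specifications
#'
#' Compares a treatment coefficient between the fixed-effects model
#' without country trends and the random-trend model:
#' \deqn{Z = (\hat\rho_{FECS} - \hat\rho_{FE}) /
#'   \sqrt{SE_{FECS}^2 + SE_{FE}^2}}
#' with cluster-robust SEs and a two-sided normal reference. Non-rejection
#' is consistent with country trends being uncorrelated with the treatment,
#' i.e. with the parallel-trend assumption.
#'
#' @param fe_fit `hfs_fefit` from [fit_twfe()].
#' @param trend_fit `hfs_trendfit` from [fit_random_trend()] on the same
#'   outcome and sample definition.
#' @param param coefficient name (`"SHI"` or `"GOV"`).
#' @return `hfs_test_result`.
#' @export
clogg_test <- function(fe_fit, trend_fit, param) {
  stopifnot(inherits(fe_fit, "hfs_fefit"), inherits(trend_fit, "hfs_trendfit"))
  if (!identical(fe_fit$outcome, trend_fit$outcome))
    stop("fits are on different outcomes: ", fe_fit$outcome, " vs ",
         trend_fit$outcome)
  if (!param %in% names(fe_fit$coefficients) ||
      !param %in% names(trend_fit$coefficients))
    stop("coefficient ", param, " missing from one of the fits")
  d <- trend_fit$coefficients[[param]] - fe_fit$coefficients[[param]]
  se <- sqrt(trend_fit$se[[param]]^2 + fe_fit$se[[param]]^2)
  z <- d / se
  test_result(paste0("clogg_", param), z, "normal",
              2 * stats::pnorm(-abs(z)),
              components = list(rho_fe = fe_fit$coefficients[[param]],
                                rho_fecs = trend_fit$coefficients[[param]],
                                se_fe = fe_fit$se[[param]],
                                se_fecs = trend_fit$se[[param]]))
}

#' Nonlinear parallel-trend ratio restriction test
#'
#' In the differential-trend model the parallel-trend assumption implies
#' that the treatment-specific trend loading vanishes, testable as the
#' nonlinear restriction
#' \eqn{(\sum_{t \ge 2} \rho_t) / (\sum_{t \ge 2} \beta_t) = 0} on the
#' treatment-by-year interactions \eqn{\rho_t} and the year main effects
#' \eqn{\beta_t}. The ratio's variance comes from the delta method on the
#' joint cluster-robust covariance; the Wald statistic is referred to
#' chi-squared(1). When the denominator is indistinguishable from zero the
#' ratio is undefined; a numerator-only Wald test is returned, labelled in
#' `note`.
#'
#' @param fit `hfs_difftrend`.
#' @param which treatment name.
#' @param denom_tol absolute tolerance below which the year-effect sum is
#'   treated as zero (default 1e-6).
#' @return `hfs_test_result` with components `num` (interaction sum),
#'   `denom` (year-effect sum), `ratio`, `se_ratio`.
#' @export
pta_ratio_test <- function(fit, which, denom_tol = 1e-6) {
  stopifnot(inherits(fit, "hfs_difftrend"))
  ints <- fit$interaction_terms[[which]]
  if (is.null(ints) || !length(ints))
    stop("fit has no interaction terms for ", which)
  yrs <- fit$year_terms
  if (!length(yrs)) stop("fit has no year main effects")
  b <- fit$coefficients
  num <- sum(b[ints])
  den <- sum(b[yrs])
  idx <- c(ints, yrs)
  V <- fit$vcov[idx, idx]

  if (abs(den) < denom_tol) {
    a <- stats::setNames(numeric(length(idx)), idx)
    a[ints] <- 1
    v_num <- as.numeric(t(a) %*% V %*% a)
    w <- num^2 / v_num
    return(test_result(paste0("pta_ratio_", which), w, "chisq(1)",
                       stats::pchisq(w, 1, lower.tail = FALSE),
                       components = list(num = num, denom = den,
                                         ratio = NA_real_,
                                         se_ratio = NA_real_),
                       note = "denominator near zero; ratio undefined, numerator-only Wald reported"))
  }

  r <- num / den
  grad <- stats::setNames(numeric(length(idx)), idx)
  grad[ints] <- 1 / den
  grad[yrs] <- -num / den^2
  v_r <- as.numeric(t(grad) %*% V %*% grad)
  w <- r^2 / v_r
  test_result(paste0("pta_ratio_", which), w, "chisq(1)",
              stats::pchisq(w, 1, lower.tail = FALSE),
              components = list(num = num, denom = den, ratio = r,
                                se_ratio = sqrt(v_r)))
}

#' Lead-based reverse-causality (Granger-style) test
#'
#' Adds one-year leads of the treatment dummies to the chosen
#' specification and t-tests each lead against zero (cluster-robust,
#' t(G-1)). A nonzero lead coefficient suggests that transitions
#' anticipate the outcome, i.e. that endogeneity is not appropriately
#' addressed.
#'
#' @param panel panel with treatment dummies.
#' @param outcome outcome column.
#' @param model `"twfe"`, `"trend"` or `"difftrend"`.
#' @param treatments treatment columns.
#' @param controls control columns.
#' @return named list of `hfs_test_result`, one per treatment; attribute
#'   `fit` holds the refitted model.
#' @export
lead_test <- function(panel, outcome, model = c("twfe", "trend", "difftrend"),
                      treatments = c("SHI", "GOV"), controls = character()) {
  model <- match.arg(model)
  if (length(unique(panel$year)) < 2)
    stop("cannot construct leads on a single-year panel")
  aug <- add_treatment_leads_lags(panel, treatments, leads = 1)
  leads <- paste0(treatments, "_lead1")
  fit <- switch(model,
    twfe = fit_core(aug, outcome, rhs = c(treatments, leads),
                    controls = controls, model_name = "twfe+leads",
                    treatments = treatments),
    trend = fit_core(aug, outcome, rhs = c(treatments, leads),
                     controls = controls, trend = TRUE,
                     model_name = "trend+leads", treatments = treatments),
    difftrend = {
      f <- fit_difftrend(aug, outcome, treatments = treatments,
                         controls = c(leads, controls))
      f
    })
  out <- list()
  for (j in seq_along(treatments)) {
    nm <- leads[j]
    if (!nm %in% names(fit$coefficients))
      stop("lead column ", nm, " dropped as collinear; test undefined")
    tstat <- fit$tstat[[nm]]
    out[[treatments[j]]] <- test_result(
      paste0("lead_", treatments[j], "_", model), tstat,
      sprintf("t(%d)", fit$df), 2 * stats::pt(-abs(tstat), fit$df),
      components = list(estimate = fit$coefficients[[nm]],
                        se = fit$se[[nm]]))
  }
  attr(out, "fit") <- fit
  out
}

#' Test of equal government and SHI transition effects
#'
#' Wald/t test of \eqn{\rho_1 - \rho_2 = 0} using the joint cluster-robust
#' covariance: \eqn{t = (\hat\rho_1 - \hat\rho_2) /
#' \sqrt{v_{11} + v_{22} - 2 v_{12}}} with t(G-1) reference. For a
#' differential-trend fit the comparison is between the two mean impacts.
#'
#' @param fit `hfs_fefit` or `hfs_difftrend`.
#' @param params the two coefficients to compare (default SHI vs GOV).
#' @return `hfs_test_result`.
#' @export
coef_diff_test <- function(fit, params = c("SHI", "GOV")) {
  stopifnot(length(params) == 2)
  if (inherits(fit, "hfs_difftrend")) {
    T <- length(fit$year_levels)
    a <- stats::setNames(numeric(length(fit$coefficients)),
                         names(fit$coefficients))
    a[params[1]] <- 1
    a[fit$interaction_terms[[params[1]]]] <- 1 / (T - 1)
    a[params[2]] <- -1
    a[fit$interaction_terms[[params[2]]]] <- -1 / (T - 1)
    d <- sum(a * fit$coefficients)
    v <- as.numeric(t(a) %*% fit$vcov %*% a)
  } else {
    if (!all(params %in% names(fit$coefficients)))
      stop("fit lacks coefficients ", paste(params, collapse = ", "))
    V <- fit$vcov[params, params]
    if (any(!is.finite(V))) stop("missing covariance elements")
    d <- fit$coefficients[[params[1]]] - fit$coefficients[[params[2]]]
    v <- V[1, 1] + V[2, 2] - 2 * V[1, 2]
  }
  stat <- if (d == 0) 0 else d / sqrt(v)
  test_result(paste0("diff_", params[1], "_", params[2]), stat,
              sprintf("t(%d)", fit$df), 2 * stats::pt(-abs(stat), fit$df),
              components = list(difference = d, se = sqrt(v)))
}

#' Goodman-Bacon timing-group decomposition
#'
#' For the absorbing-switch sub-design (never-treated countries plus
#' countries whose switch to `which` is absorbing), decomposes the binary
#' two-way fixed-effects coefficient (no controls) into weighted 2x2
#' difference-in-differences comparisons across timing groups: each
#' treated cohort vs the never-treated, earlier vs later cohorts (later
#' still untreated as controls), and later vs earlier cohorts (the
#' "already treated as control" comparisons that can carry problematic
#' negative-weight behaviour under effect dynamics). Weights sum to one
#' and the weighted 2x2 estimates reproduce the sub-panel TWFE coefficient
#' exactly on a balanced panel.
#'
#' @param panel panel data.frame.
#' @param labels HFS label vector aligned with `panel` rows.
#' @param outcome outcome column.
#' @param which treatment destination, `"GOV"` or `"SHI"`.
#' @return object of class `hfs_bacon`: data.frame `weights` (`comparison`,
#'   `treated_group`, `control_group`, `weight`, `estimate`), scalars
#'   `twfe`, `problematic_share` (total weight on later-vs-earlier
#'   comparisons), `n_countries`, `n_obs`.
#' @export
bacon_weights <- function(panel, labels, outcome, which = c("GOV", "SHI")) {
  which <- match.arg(which)
  d <- data.frame(country_id = panel$country_id, year = panel$year,
                  y = panel[[outcome]], lab = labels,
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), ]

  # keep never-treated (all-OOP) countries and absorbing switchers to `which`
  keep <- vapply(split(d, d$country_id), function(g) {
    g <- g[order(g$year), ]
    tr <- g$lab == which
    if (!any(tr)) return(all(g$lab == "OOP"))
    if (all(tr)) return(FALSE)                      # exposed throughout
    all(g$lab[!tr] == "OOP") && all(diff(tr) >= 0)  # 0...01...1 pattern
  }, logical(1))
  d <- d[d$country_id %in% names(keep)[keep], ]

  # balanced window: countries observed in all years of the panel window
  yrs <- sort(unique(d$year))
  T <- length(yrs)
  full <- vapply(split(d$year, d$country_id),
                 function(v) length(v) == T && all(sort(v) == yrs),
                 logical(1))
  d <- d[d$country_id %in% names(full)[full], ]
  if (!nrow(d)) stop("no balanced countries in the restricted sub-panel")

  d$treat <- as.numeric(d$lab == which)
  first_tr <- vapply(split(d, d$country_id), function(g)
    if (any(g$treat == 1)) min(g$year[g$treat == 1]) else NA_integer_,
    numeric(1))
  cohorts <- sort(unique(first_tr[!is.na(first_tr)]))
  # treated throughout = no untreated periods: unusable as a timing group
  cohorts <- cohorts[cohorts > yrs[1]]
  n_never <- sum(is.na(first_tr)) +
    sum(!is.na(first_tr) & first_tr <= yrs[1])
  if (length(cohorts) + (n_never > 0) < 2)
    stop("need at least 2 timing groups for the decomposition")

  n_by <- table(first_tr[!is.na(first_tr) & first_tr > yrs[1]])
  n_tot <- length(first_tr)
  grp_n <- c(stats::setNames(as.numeric(n_by), names(n_by)),
             never = n_never)
  grp_share <- grp_n / n_tot
  D_of <- function(k) sum(yrs >= k) / T      # treated share of periods

  ybar <- function(ids, lo, hi) {
    sel <- d$country_id %in% ids & d$year >= lo & d$year <= hi
    mean(d$y[sel])
  }
  ids_of <- function(k) names(first_tr)[!is.na(first_tr) & first_tr == k]
  never_ids <- names(first_tr)[is.na(first_tr) | first_tr <= yrs[1]]

  rows <- list()
  add <- function(comparison, tg, cg, s_num, est) {
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, treated_group = as.character(tg),
      control_group = as.character(cg), s_num = s_num, estimate = est,
      stringsAsFactors = FALSE)
  }
  did <- function(t_ids, c_ids, pre_lo, pre_hi, post_lo, post_hi) {
    (ybar(t_ids, post_lo, post_hi) - ybar(t_ids, pre_lo, pre_hi)) -
      (ybar(c_ids, post_lo, post_hi) - ybar(c_ids, pre_lo, pre_hi))
  }

  for (k in cohorts) {
    Dk <- D_of(k)
    if (n_never > 0) {
      nk <- grp_share[[as.character(k)]]; nu <- grp_share[["never"]]
      nku <- nk / (nk + nu)
      s <- (nk + nu)^2 * nku * (1 - nku) * Dk * (1 - Dk)
      est <- did(ids_of(k), never_ids, yrs[1], k - 1, k, yrs[T])
      add("treated_vs_never", k, "never", s, est)
    }
    for (l in cohorts[cohorts > k]) {
      Dl <- D_of(l)
      nk <- grp_share[[as.character(k)]]; nl <- grp_share[[as.character(l)]]
      nkl <- nk / (nk + nl)
      # earlier k vs later l, window before l treats (l is a clean control)
      Dkl_k <- (Dk - Dl) / (1 - Dl)
      s_e <- ((nk + nl) * (1 - Dl))^2 * nkl * (1 - nkl) * Dkl_k * (1 - Dkl_k)
      est_e <- did(ids_of(k), ids_of(l), yrs[1], k - 1, k, l - 1)
      add("early_vs_late", k, l, s_e, est_e)
      # later l vs earlier k, window after k treats (k already treated)
      Dkl_l <- Dl / Dk
      s_l <- ((nk + nl) * Dk)^2 * nkl * (1 - nkl) * Dkl_l * (1 - Dkl_l)
      est_l <- did(ids_of(l), ids_of(k), k, l - 1, l, yrs[T])
      add("late_vs_early", l, k, s_l, est_l)
    }
  }
  w <- do.call(rbind, rows)
  w$weight <- w$s_num / sum(w$s_num)
  w$s_num <- NULL

  # sub-panel TWFE coefficient (binary treatment, no controls)
  d$treat_d <- d$treat
  fit <- fit_core(d, "y", rhs = "treat_d", model_name = "bacon_twfe",
                  treatments = "treat_d")
  structure(list(weights = w,
                 twfe = fit$coefficients[["treat_d"]],
                 weighted_sum = sum(w$weight * w$estimate),
                 problematic_share = sum(w$weight[w$comparison == "late_vs_early"]),
                 n_countries = length(unique(d$country_id)),
                 n_obs = nrow(d)),
            class = "hfs_bacon")
}

#' @export
print.hfs_bacon <- function(x, ...) {
  cat(sprintf("<Goodman-Bacon decomposition> TWFE = %.4f (weighted 2x2 sum %.4f)\n",
              x$twfe, x$weighted_sum))
  agg <- stats::aggregate(weight ~ comparison, data = x$weights, sum)
  print(agg)
  cat(sprintf("weight on already-treated-as-control comparisons: %.1f%%\n",
              100 * x$problematic_share))
  invisible(x)
}

#' Summarize a collection of p-values
#'
#' Bin counts over [0, 1] plus the shares significant at 5\% and 10\%,
#' the reporting style used for batteries of specification tests.
#'
#' @param p_values numeric vector of p-values (or list of
#'   `hfs_test_result`).
#' @param breaks histogram breaks (default 10 equal bins).
#' @return list: `table` (data.frame `bin`, `count`), `n`,
#'   `share_below_05`, `share_below_10`.
#' @export
pvalue_histogram <- function(p_values, breaks = seq(0, 1, 0.1)) {
  if (is.list(p_values) && !is.numeric(p_values))
    p_values <- vapply(p_values, function(x) x$p_value, numeric(1))
  if (!length(p_values)) stop("no p-values supplied")
  stopifnot(all(p_values >= 0 & p_values <= 1))
  cnt <- table(cut(p_values, breaks = breaks, include.lowest = TRUE,
                   right = TRUE))
  list(table = data.frame(bin = names(cnt), count = as.integer(cnt)),
       n = length(p_values),
       share_below_05 = mean(p_values < 0.05),
       share_below_10 = mean(p_values < 0.10))
}
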