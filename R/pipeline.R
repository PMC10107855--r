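#' @title Full analysis pipeline
#' @description One deterministic driver for the whole study analog:
#' simulate (or load) a panel, classify country-years into financing
#' systems, fit all outcomes under the main, random-trend and
#' differential-trend specifications, run the specification-test battery,
#' and emit a machine-readable report with coefficient tables, percent
#' translations for logged outcomes, transition counts and p-value
#' summaries.
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param input `"simulate"` or a path to a panel CSV.
#' @param sim_cfg `hfs_sim_config` used when `input = "simulate"`.
#' @param classify `"kmeans"`, `"argmax"` or `"threshold"`.
#' @param k clusters for k-means; `threshold` OOP threshold in percent.
#' @param threshold OOP threshold when `classify = "threshold"`.
#' @param outcomes outcome columns to analyse (log names for logged
#'   outcomes).
#' @param controls control columns.
#' @param contextual contextual factors for interaction fits (may be
#'   empty).
#' @param models specifications to fit, subset of
#'   `c("twfe", "trend", "difftrend")`.
#' @param seed seed used for simulation and clustering.
#' @param out_dir optional directory: report JSON and CSV tables written
#'   there.
#' @return list of class `hfs_run_config`.
#' @export
run_config <- function(input = "simulate",
                       sim_cfg = NULL,
                       classify = c("kmeans", "argmax", "threshold"),
                       k = 3, threshold = 50,
                       outcomes = c("log_the_pc", "imm_idx", "le",
                                    "log_u5m", "log_mm", "cat10"),
                       controls = c("log_gdp_pc", "educ_enroll", "water_pct",
                                    "urban_pct", "gini", "pop65_pct",
                                    "pop14_pct", "gov_eff", "corr_ctrl"),
                       contextual = character(),
                       models = c("twfe", "trend", "difftrend"),
                       seed = 1,
                       out_dir = NULL) {
  classify <- match.arg(classify)
  if (!length(outcomes)) stop("outcome list must not be empty")
  models <- match.arg(models, several.ok = TRUE)
  if (identical(input, "simulate") && is.null(sim_cfg))
    sim_cfg <- sim_config(seed = seed)
  structure(list(input = input, sim_cfg = sim_cfg, classify = classify,
                 k = k, threshold = threshold, outcomes = outcomes,
                 controls = controls, contextual = contextual,
                 models = models, seed = seed, out_dir = out_dir),
            class = "hfs_run_config")
}

logged_outcome <- function(nm) grepl("^log_", nm)

#' Run the full analysis
#'
#' Deterministic given the seed. Returns (and optionally writes) a report
#' containing: the cluster summary (centroid table and group counts per
#' year), transition events and counts by direction, the coefficient
#' matrix outcomes x treatments with cluster-robust SEs and significance
#' stars, percent translations for logged outcomes, the specification-test
#' p-value table with histogram summaries, and per-model result bundles.
#'
#' @param cfg `hfs_run_config`.
#' @return list of class `hfs_report`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "hfs_run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  panel <- stage("input", {
    if (identical(cfg$input, "simulate")) {
      sim <- simulate_panel(cfg$sim_cfg)
      sim$panel
    } else read_panel(cfg$input)
  })
  panel <- stage("transform", {
    to_log <- sub("^log_", "", cfg$outcomes[logged_outcome(cfg$outcomes)])
    if (length(to_log)) log_transform_outcomes(panel, to_log) else panel
  })

  cls <- stage("classify", {
    if (cfg$classify == "kmeans") {
      m <- fit_kmeans(panel, k = cfg$k, seed = cfg$seed)
      if (is.null(m$labels))
        stop("k-means labelling ambiguous; use argmax or re-seed")
      list(labels = m$labels, model = m)
    } else if (cfg$classify == "argmax") {
      list(labels = classify_argmax(panel$gov_pct, panel$shi_pct,
                                    panel$oop_pct), model = NULL)
    } else {
      list(labels = classify_threshold(panel$gov_pct, panel$shi_pct,
                                       panel$oop_pct, t = cfg$threshold),
           model = NULL)
    }
  })
  labels <- cls$labels
  dm <- labels_to_dummies(labels)
  panel$SHI <- dm$SHI
  panel$GOV <- dm$GOV

  transitions <- stage("transitions", detect_transitions_panel(panel, labels))
  tr_counts <- if (nrow(transitions))
    stats::aggregate(country_id ~ from_label + to_label, transitions,
                     function(x) length(unique(x)))
  else data.frame(from_label = character(), to_label = character(),
                  country_id = integer())
  names(tr_counts)[3] <- "n_countries"

  fits <- list(); coef_rows <- list(); tests <- list(); bundles <- list()
  star <- function(p) if (p < 0.01) "***" else if (p < 0.05) "**"
    else if (p < 0.1) "*" else ""

  for (oc in cfg$outcomes) {
    f_tw <- if ("twfe" %in% cfg$models)
      stage(paste0("twfe:", oc),
            fit_twfe(panel, oc, controls = cfg$controls)) else NULL
    f_tr <- if ("trend" %in% cfg$models)
      stage(paste0("trend:", oc),
            fit_random_trend(panel, oc, controls = cfg$controls)) else NULL
    f_dt <- if ("difftrend" %in% cfg$models)
      stage(paste0("difftrend:", oc),
            fit_difftrend(panel, oc, controls = cfg$controls)) else NULL
    fits[[oc]] <- list(twfe = f_tw, trend = f_tr, difftrend = f_dt)

    if (!is.null(f_tw)) {
      for (tr in c("GOV", "SHI")) {
        est <- f_tw$coefficients[[tr]]; p <- f_tw$p_value[[tr]]
        coef_rows[[paste(oc, tr)]] <- data.frame(
          outcome = oc, treatment = tr, estimate = est, se = f_tw$se[[tr]],
          p_value = p, stars = star(p),
          pct_effect = if (logged_outcome(oc)) round(pct_effect(est), 1)
                       else NA_real_,
          stringsAsFactors = FALSE)
      }
      bundles[[paste0("twfe_", oc)]] <- result_bundle(
        "twfe", oc, coef_table(f_tw), n_obs = f_tw$n_obs,
        n_countries = f_tw$n_countries, r2_within = f_tw$r2_within,
        r2_adj = f_tw$r2_adj)
    }

    # specification-test battery for this outcome
    if (!is.null(f_tw) && !is.null(f_tr)) {
      for (tr in c("SHI", "GOV")) {
        t1 <- stage(paste0("clogg:", oc), clogg_test(f_tw, f_tr, tr))
        tests[[paste0("clogg_", tr, "_", oc)]] <- data.frame(
          outcome = oc, treatment = tr, test = "clogg",
          statistic = t1$statistic, p_value = t1$p_value,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(f_dt)) {
      for (tr in c("SHI", "GOV")) {
        t2 <- stage(paste0("pta_ratio:", oc), pta_ratio_test(f_dt, tr))
        tests[[paste0("ratio_", tr, "_", oc)]] <- data.frame(
          outcome = oc, treatment = tr, test = "pta_ratio",
          statistic = t2$statistic, p_value = t2$p_value,
          stringsAsFactors = FALSE)
      }
    }
    lt <- stage(paste0("lead:", oc),
                lead_test(panel, oc, model = "twfe",
                          controls = cfg$controls))
    for (tr in names(lt))
      tests[[paste0("lead_", tr, "_", oc)]] <- data.frame(
        outcome = oc, treatment = tr, test = "lead",
        statistic = lt[[tr]]$statistic, p_value = lt[[tr]]$p_value,
        stringsAsFactors = FALSE)
    if (!is.null(f_tw)) {
      t3 <- coef_diff_test(f_tw, params = c("GOV", "SHI"))
      tests[[paste0("diff_", oc)]] <- data.frame(
        outcome = oc, treatment = "GOV-SHI", test = "coef_diff",
        statistic = t3$statistic, p_value = t3$p_value,
        stringsAsFactors = FALSE)
    }
  }

  # contextual-factor interactions (first outcome set by default empty)
  interactions <- list()
  for (cf in cfg$contextual) {
    for (oc in cfg$outcomes) {
      fi <- stage(paste0("interaction:", oc, ":", cf),
                  fit_interaction(panel, oc, cf, controls = cfg$controls))
      interactions[[paste0(oc, ":", cf)]] <- coef_table(
        fi, c("SHI", "GOV", cf, fi$cf_terms))
    }
  }

  coef_matrix <- do.call(rbind, coef_rows)
  rownames(coef_matrix) <- NULL
  test_table <- do.call(rbind, tests)
  rownames(test_table) <- NULL
  pta_tab <- test_table[test_table$test %in% c("clogg", "pta_ratio"), ]
  report <- structure(list(
    seed = cfg$seed,
    cluster_summary = if (!is.null(cls$model)) list(
      centroids = round(cls$model$centroids, 2),
      inertia = cls$model$inertia,
      counts_per_year = as.data.frame(table(
        year = panel$year, label = labels))) else NULL,
    transitions = transitions, transition_counts = tr_counts,
    coefficients = coef_matrix,
    tests = test_table,
    pta_pvalue_summary = pvalue_histogram(pta_tab$p_value),
    lead_pvalue_summary = pvalue_histogram(
      test_table$p_value[test_table$test == "lead"]),
    interactions = interactions,
    bundles = bundles,
    fits = fits
  ), class = "hfs_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(coef_matrix,
                     file.path(cfg$out_dir, "coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(test_table, file.path(cfg$out_dir, "tests.csv"),
                     row.names = FALSE)
    json <- report[setdiff(names(report), c("fits", "bundles"))]
    jsonlite::write_json(json, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}

#' @export
print.hfs_report <- function(x, ...) {
  cat("<hfspanel report> seed", x$seed, "\n")
  cat("\nTransitions:\n"); print(x$transition_counts)
  cat("\nMain two-way FE estimates:\n")
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), p_value = round(p_value, 3)))
  cat(sprintf("\nPTA tests: %d, share p<0.05 = %.2f; lead tests: %d, share p<0.05 = %.2f\n",
              x$pta_pvalue_summary$n, x$pta_pvalue_summary$share_below_05,
              x$lead_pvalue_summary$n, x$lead_pvalue_summary$share_below_05))
  invisible(x)
}

#' Compare a report's estimates against reference (true) values
#'
#' @param report `hfs_report`.
#' @param reference data.frame with columns `outcome`, `treatment`,
#'   `truth`.
#' @return data.frame with `estimate`, `truth`, `deviation`, `abs_z`
#'   (deviation over reported SE) and `covered` (truth inside the 95\%
#'   cluster-robust CI).
#' @export
compare_to_reference <- function(report, reference) {
  stopifnot(inherits(report, "hfs_report"), is.data.frame(reference))
  need <- c("outcome", "treatment", "truth")
  if (!all(need %in% names(reference)))
    stop("reference needs columns: ", paste(need, collapse = ", "))
  m <- merge(report$coefficients, reference, by = c("outcome", "treatment"))
  if (nrow(m) < nrow(reference)) {
    missing_keys <- setdiff(paste(reference$outcome, reference$treatment),
                            paste(m$outcome, m$treatment))
    stop("reference keys not found in report: ",
         paste(missing_keys, collapse = "; "))
  }
  m$deviation <- m$estimate - m$truth
  m$abs_z <- abs(m$deviation) / m$se
  crit <- stats::qnorm(0.975)
  m$covered <- m$abs_z <= crit
  m[, c("outcome", "treatment", "estimate", "se", "truth", "deviation",
        "abs_z", "covered")]
}
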