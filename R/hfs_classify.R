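#' @title Classification of country-years into predominant financing systems
#' @description Assigns each country-year to an OOP-, government- or
#' SHI-predominant health financing system (HFS) by k-means clustering on
#' raw financing shares, provides the simpler argmax and OOP-threshold
#' classification rules, diagnostics for the number of clusters, and
#' detection of durable financing transitions.
#' @name hfs_classify
NULL

hfs_levels <- function() c("OOP", "GOV", "SHI")

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

# one Lloyd run from given centers; inertia must be nonincreasing
lloyd_run <- function(x, centers, max_iter = 300) {
  n <- nrow(x); k <- nrow(centers)
  x2 <- rowSums(x^2)
  assign_step <- function(centers) {
    # squared distances via ||x||^2 - 2 x.c + ||c||^2
    cross <- x %*% t(centers)
    d <- x2 - 2 * cross + matrix(rowSums(centers^2), n, k, byrow = TRUE)
    cl <- max.col(-d, ties.method = "first")
    dmin <- pmax(d[cbind(seq_len(n), cl)], 0)
    list(cl = cl, d = dmin, wss = sum(dmin))
  }
  a <- assign_step(centers)
  inertia <- a$wss
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      idx <- a$cl == j
      if (!any(idx)) {
        # empty cluster: relocate its center onto the worst-fit point
        # (cannot increase inertia); with exact duplicates everywhere the
        # center just lands on a point and the cluster may stay empty
        centers[j, ] <- x[which.max(a$d), ]
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    a_new <- assign_step(centers)
    if (a_new$wss > inertia + 1e-8 * (1 + inertia))
      stop("internal error: Lloyd iteration increased inertia")
    converged <- identical(a_new$cl, a$cl)
    a <- a_new
    inertia <- a$wss
    if (converged) break
  }
  list(cluster = a$cl, centers = centers, inertia = inertia, iters = it)
}

#' Pooled k-means clustering of financing shares
#'
#' All country-years with complete share data are pooled into one
#' clustering (labels stay comparable over time). Lloyd's algorithm with
#' k-means++ initialization, best of `n_init` restarts by within-cluster
#' sum of squares; deterministic given `seed`. Shares enter unstandardized:
#' all inputs are percentages on a common scale.
#'
#' @param panel panel data.frame.
#' @param k number of clusters (default 3).
#' @param seed integer seed for the restarts.
#' @param n_init number of k-means++ restarts (default 50).
#' @param cols share columns to cluster on; default government, SHI and
#'   OOP shares. Supplying all seven scheme shares gives the
#'   all-arrangements variant.
#' @param max_iter Lloyd iteration cap per restart.
#' @return object of class `hfs_cluster_model`: `k`, `centroids`,
#'   `assignment` (cluster index per row of `panel`, NA where shares
#'   incomplete), `inertia`, `label_map` (when `k = 3` and the argmax
#'   labelling is unambiguous; otherwise NULL), `labels` (mapped labels per
#'   row when `label_map` exists), `cols`, `seed`, `n_init`.
#' @export
fit_kmeans <- function(panel, k = 3, seed = 1, n_init = 50,
                       cols = c("gov_pct", "shi_pct", "oop_pct"),
                       max_iter = 300) {
  stopifnot(k >= 1, n_init >= 1)
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("missing share columns: ", paste(miss, collapse = ", "))
  x_all <- as.matrix(panel[, cols])
  ok <- stats::complete.cases(x_all)
  x <- x_all[ok, , drop = FALSE]
  if (nrow(x) < k)
    stop(sprintf("only %d complete-share observations for k = %d", nrow(x), k))

  best <- NULL
  with_local_seed(seed, {
    for (i in seq_len(n_init)) {
      run <- lloyd_run(x, kmeanspp_init(x, k), max_iter)
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })

  assignment <- rep(NA_integer_, nrow(panel))
  assignment[ok] <- best$cluster
  centroids <- best$centers
  colnames(centroids) <- cols

  model <- structure(list(
    k = k, centroids = centroids, assignment = assignment,
    inertia = best$inertia, cols = cols, seed = seed, n_init = n_init,
    label_map = NULL, labels = NULL
  ), class = "hfs_cluster_model")
  if (k == 3 && all(c("gov_pct", "shi_pct", "oop_pct") %in% cols)) {
    lm_try <- tryCatch(label_clusters(model), error = function(e) NULL)
    if (!is.null(lm_try)) {
      model$label_map <- lm_try
      model$labels <- unname(lm_try[assignment])
    }
  }
  model
}

#' @export
print.hfs_cluster_model <- function(x, ...) {
  cat(sprintf("<k-means HFS model> k = %d, inertia = %.1f\n", x$k, x$inertia))
  print(round(x$centroids, 2))
  if (!is.null(x$label_map))
    cat("labels:", paste(seq_along(x$label_map), x$label_map,
                         sep = "->", collapse = ", "), "\n")
  invisible(x)
}

#' Label clusters by the predominant share of their centroid
#'
#' Each cluster is labelled by the argmax coordinate of its centroid
#' (government share -> GOV, SHI share -> SHI, OOP share -> OOP). Requires
#' a 3-cluster model on the three major shares; errors if two centroids
#' share an argmax (ambiguous solution - re-cluster or use an alternative
#' rule).
#'
#' @param model `hfs_cluster_model` with `k = 3`.
#' @return named character vector: cluster index -> label.
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "hfs_cluster_model"))
  if (model$k != 3)
    stop("cluster labelling is defined for k = 3")
  cols <- c("gov_pct", "shi_pct", "oop_pct")
  if (!all(cols %in% colnames(model$centroids)))
    stop("centroids must include gov_pct, shi_pct and oop_pct")
  lab_of <- c(gov_pct = "GOV", shi_pct = "SHI", oop_pct = "OOP")
  arg <- apply(model$centroids[, cols], 1, function(z) names(z)[which.max(z)])
  labs <- unname(lab_of[arg])
  if (anyDuplicated(labs))
    stop("ambiguous clustering: two centroids share the same predominant share (",
         paste(labs, collapse = ", "), ")")
  stats::setNames(labs, seq_len(3))
}

#' Classify one or more country-years by the largest share
#'
#' The "highest value" rule: the label of the largest of the government,
#' SHI and OOP shares. Ties break in the order OOP > GOV > SHI
#' (conservatively toward the OOP reference category).
#'
#' @param gov_pct,shi_pct,oop_pct share vectors (percent of THE).
#' @return character vector of labels.
#' @export
classify_argmax <- function(gov_pct, shi_pct, oop_pct) {
  if (anyNA(gov_pct) || anyNA(shi_pct) || anyNA(oop_pct))
    stop("shares must be complete for argmax classification")
  m <- cbind(OOP = oop_pct, GOV = gov_pct, SHI = shi_pct)
  colnames(m)[max.col(m, ties.method = "first")]
}

#' Classify by an OOP threshold
#'
#' OOP-predominant if the OOP share exceeds threshold `t`; otherwise the
#' larger of the government and SHI shares decides (GOV on ties).
#'
#' @param gov_pct,shi_pct,oop_pct share vectors.
#' @param t threshold in percent, in (0, 100); `t = 0` is allowed and makes
#'   any positive OOP share OOP-predominant.
#' @return character vector of labels.
#' @export
classify_threshold <- function(gov_pct, shi_pct, oop_pct, t = 50) {
  if (anyNA(gov_pct) || anyNA(shi_pct) || anyNA(oop_pct))
    stop("shares must be complete for threshold classification")
  stopifnot(t >= 0, t < 100)
  ifelse(oop_pct > t, "OOP", ifelse(gov_pct >= shi_pct, "GOV", "SHI"))
}

#' Diagnostics for choosing the number of clusters
#'
#' Scree-style diagnostics over k = 1..k_max: within-cluster sum of squares
#' WSS(k), log WSS(k), the explained-variance ratio eta2(k) = 1 -
#' WSS(k)/WSS(1), and the proportional reduction in error PRE(k) =
#' (WSS(k-1) - WSS(k)) / WSS(k-1). The `elbow` is the k after which the
#' PRE drops most, i.e. argmax over k of PRE(k) - PRE(k+1).
#'
#' @param panel panel data.frame.
#' @param k_max maximum k (>= 2).
#' @param seed seed passed to each [fit_kmeans()].
#' @param n_init restarts per k (default 10; the per-k fits are repeated
#'   across a scree, so fewer restarts than a final classification fit).
#' @param cols share columns.
#' @return object of class `hfs_kselect`: data.frame `table` with columns
#'   `k`, `wss`, `log_wss`, `eta2`, `pre`, plus `elbow`.
#' @export
kselect_diagnostics <- function(panel, k_max = 6, seed = 1, n_init = 10,
                                cols = c("gov_pct", "shi_pct", "oop_pct")) {
  stopifnot(k_max >= 2)
  wss <- numeric(k_max)
  for (k in seq_len(k_max))
    wss[k] <- fit_kmeans(panel, k = k, seed = seed + k, n_init = n_init,
                         cols = cols)$inertia
  eta2 <- 1 - wss / wss[1]
  pre <- c(NA_real_, (wss[-k_max] - wss[-1]) / wss[-k_max])
  tab <- data.frame(k = seq_len(k_max), wss = wss,
                    log_wss = ifelse(wss > 0, log(wss), -Inf),
                    eta2 = eta2, pre = pre)
  drop_after <- pre[-k_max] - pre[-1]          # indexed by k = 1..k_max-1
  cand <- seq(2, k_max - 1)                    # need PRE(k) and PRE(k+1)
  elbow <- cand[which.max(drop_after[cand])]
  structure(list(table = tab, elbow = elbow), class = "hfs_kselect")
}

#' @export
print.hfs_kselect <- function(x, ...) {
  print(transform(x$table, wss = round(wss, 1), log_wss = round(log_wss, 2),
                  eta2 = round(eta2, 3), pre = round(pre, 3)))
  cat("PRE elbow at k =", x$elbow, "\n")
  invisible(x)
}

#' Detect durable financing transitions in a label series
#'
#' A health financing transition is a switch of the predominant HFS that
#' lasts at least `min_duration` consecutive observed years. Short blips
#' (runs below the duration threshold) emit nothing, and the return from a
#' blip to the previously established label is not an event either: events
#' are changes of the *established* label, where a label becomes
#' established once its run reaches `min_duration` (the initial label is
#' established by definition). A gap in the year sequence breaks a run.
#'
#' @param country_id scalar id for the reported events.
#' @param years integer years, sorted; gaps allowed.
#' @param labels labels aligned with `years`.
#' @param min_duration minimum persistence in years (default 2).
#' @return data.frame with columns `country_id`, `switch_year`,
#'   `from_label`, `to_label`, `persistence` (0 rows if none).
#' @export
detect_transitions <- function(country_id, years, labels, min_duration = 2) {
  empty <- data.frame(country_id = character(), switch_year = integer(),
                      from_label = character(), to_label = character(),
                      persistence = integer(), stringsAsFactors = FALSE)
  keep <- !is.na(labels)
  years <- years[keep]; labels <- labels[keep]
  if (length(labels) == 0) return(empty)
  o <- order(years)
  years <- years[o]; labels <- labels[o]

  # split into runs: same label over consecutive years (gap breaks a run)
  brk <- c(TRUE, labels[-1] != labels[-length(labels)] |
                 diff(years) != 1)
  run_id <- cumsum(brk)
  run_label <- tapply(labels, run_id, `[`, 1)
  run_start <- tapply(years, run_id, min)
  run_len <- tapply(years, run_id, length)

  established <- run_label[[1]]
  out <- empty
  for (r in seq_along(run_label)) {
    lab <- run_label[[r]]
    if (lab != established && run_len[[r]] >= min_duration) {
      out <- rbind(out, data.frame(
        country_id = country_id, switch_year = as.integer(run_start[[r]]),
        from_label = established, to_label = lab,
        persistence = as.integer(run_len[[r]]), stringsAsFactors = FALSE))
      established <- lab
    } else if (lab == established && run_len[[r]] >= min_duration) {
      established <- lab
    }
  }
  out
}

#' Detect transitions for every country in a labelled panel
#'
#' @param panel panel with `country_id` and `year`.
#' @param labels label vector aligned with `panel` rows.
#' @param min_duration minimum persistence (default 2).
#' @return stacked data.frame of transition events.
#' @export
detect_transitions_panel <- function(panel, labels, min_duration = 2) {
  parts <- lapply(split(seq_len(nrow(panel)), panel$country_id), function(ix)
    detect_transitions(panel$country_id[ix[1]], panel$year[ix],
                       labels[ix], min_duration))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Smooth one-year label blips
#'
#' Optional pre-regression smoothing: runs shorter than `min_duration`
#' revert to the previously established label.
#'
#' @inheritParams detect_transitions
#' @return smoothed label vector (aligned with the input order).
#' @export
smooth_labels <- function(years, labels, min_duration = 2) {
  o <- order(years)
  lab <- labels[o]; yr <- years[o]
  brk <- c(TRUE, lab[-1] != lab[-length(lab)] | diff(yr) != 1)
  run_id <- cumsum(brk)
  established <- lab[1]
  for (r in unique(run_id)) {
    ix <- which(run_id == r)
    if (length(ix) >= min_duration || lab[ix[1]] == established)
      established <- lab[ix[1]]
    else lab[ix] <- established
  }
  out <- labels
  out[o] <- lab
  out
}

#' Build treatment dummies from a label series
#'
#' SHI = 1 where the label is SHI-predominant, GOV = 1 where
#' government-predominant; OOP is the omitted reference (both zero). The
#' dummies are mutually exclusive by construction.
#'
#' @param labels character/factor labels in `{OOP, GOV, SHI}` (NA allowed).
#' @return data.frame with numeric columns `SHI`, `GOV`.
#' @export
labels_to_dummies <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels[!is.na(labels)]), hfs_levels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  data.frame(SHI = as.numeric(labels == "SHI"),
             GOV = as.numeric(labels == "GOV"))
}
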