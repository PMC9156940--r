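# Joining preceding-sleep photometry summaries with next-day behavior and
# the correlation / quartile statistics computed on the joined table.

#' Join sleep summaries with next-day behavior
#'
#' Inner join in the "next day" convention: the sleep summary of day `d`
#' pairs with behavior of day `d + 1`.  Rows present on only one side are
#' dropped and reported.
#'
#' @param sleep data.frame keyed by `mouse`, `day` with activity summaries
#'   (e.g. `nrem_activity`, `rem_activity`).
#' @param behavior data.frame keyed by `mouse`, `day`, `trial` with
#'   behavioral outcomes (occupancy columns, visit speeds, ...).
#' @return data.frame of class `link_table`, one row per behavioral trial,
#'   with sleep columns from the preceding day; `attr(, "dropped")` lists
#'   the unmatched keys.
#' @export
build_link_table <- function(sleep, behavior) {
  nl_assert(all(c("mouse", "day") %in% names(sleep)),
            "sleep needs mouse, day columns")
  nl_assert(all(c("mouse", "day", "trial") %in% names(behavior)),
            "behavior needs mouse, day, trial columns")
  s <- sleep
  s$behavior_day <- s$day + 1
  names(s)[names(s) == "day"] <- "sleep_day"
  merged <- merge(behavior, s, by.x = c("mouse", "day"),
                  by.y = c("mouse", "behavior_day"))
  if (!nrow(merged)) nl_stop("no overlapping mouse-days between sleep and behavior",
                             "no_overlap")
  b_keys <- unique(paste(behavior$mouse, behavior$day))
  m_keys <- unique(paste(merged$mouse, merged$day))
  s_keys <- unique(paste(sleep$mouse, sleep$day + 1))
  dropped <- list(behavior_days = setdiff(b_keys, m_keys),
                  sleep_days = setdiff(s_keys, m_keys))
  n_drop <- length(dropped$behavior_days) + length(dropped$sleep_days)
  if (n_drop > 0) {
    message(sprintf("build_link_table: dropped %d unmatched mouse-day key(s)",
                    n_drop))
  }
  merged <- merged[order(merged$mouse, merged$day, merged$trial), ]
  rownames(merged) <- NULL
  attr(merged, "dropped") <- dropped
  class(merged) <- c("link_table", class(merged))
  merged
}

#' Per-cluster correlation of occupancy with preceding sleep activity
#'
#' Pearson correlation (two-sided) between the chosen sleep state's activity
#' summary and each behavioral cluster's occupancy, pooled across rows
#' (mouse-day-trials), with Bonferroni correction over the number of
#' clusters.
#'
#' @param table a `link_table` with occupancy columns `occ_1 .. occ_K`.
#' @param sleep_state `"NREM"` or `"REM"`; selects the activity column
#'   `nrem_activity` / `rem_activity`.
#' @param n_clusters number of clusters (Bonferroni multiplicity), default
#'   the number of `occ_` columns.
#' @return data.frame per cluster: `cluster`, `r`, `p_raw`, `p_bonferroni`,
#'   `n`; clusters with zero occupancy variance report `NA` with
#'   `note = "zero variance"`.
#' @export
correlate_occupancy_activity <- function(table, sleep_state = c("NREM", "REM"),
                                         n_clusters = NULL) {
  sleep_state <- match.arg(sleep_state)
  act_col <- if (sleep_state == "NREM") "nrem_activity" else "rem_activity"
  nl_assert(act_col %in% names(table),
            sprintf("table lacks column %s", act_col))
  occ_cols <- grep("^occ_", names(table), value = TRUE)
  nl_assert(length(occ_cols) > 0, "table lacks occ_* occupancy columns")
  if (is.null(n_clusters)) n_clusters <- length(occ_cols)
  nl_assert(nrow(table) >= 5, "need >= 5 rows", "insufficient_data")
  act <- table[[act_col]]
  out <- do.call(rbind, lapply(seq_along(occ_cols), function(k) {
    occ <- table[[occ_cols[k]]]
    if (stats::sd(occ) < 1e-12 || stats::sd(act) < 1e-12) {
      return(data.frame(cluster = k, r = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, n = length(occ),
                        note = "zero variance"))
    }
    ct <- stats::cor.test(act, occ, method = "pearson")
    data.frame(cluster = k, r = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, ct$p.value * n_clusters),
               n = length(occ), note = "")
  }))
  rownames(out) <- NULL
  out
}

#' Quartile comparison of port-visit speeds by sleep activity
#'
#' Ranks mouse-days by the chosen sleep state's activity, pools the
#' individual port-visit speeds of the lower and upper quartile of days, and
#' compares them with a two-sided Mann-Whitney U test (exact for small
#' tie-free samples, normal approximation with tie correction otherwise),
#' Bonferroni-adjusted over `n_comparisons`.
#'
#' @param table a `link_table` with a `visit_speeds` list-column (speeds per
#'   trial row) and the activity column for `sleep_state`.
#' @param sleep_state `"NREM"` or `"REM"`.
#' @param n_comparisons Bonferroni multiplicity (number of such comparisons
#'   in the run), default 1.
#' @return list: `low_speeds`, `high_speeds` (pooled cm/s), `U`, `p`,
#'   `p_adjusted`, `low_days`, `high_days`.
#' @export
quartile_speed_comparison <- function(table, sleep_state = c("NREM", "REM"),
                                      n_comparisons = 1) {
  sleep_state <- match.arg(sleep_state)
  act_col <- if (sleep_state == "NREM") "nrem_activity" else "rem_activity"
  day_key <- paste(table$mouse, table$day)
  days <- !duplicated(day_key)
  day_tab <- data.frame(key = day_key[days], act = table[[act_col]][days])
  if (nrow(day_tab) < 8) nl_stop("need >= 8 mouse-days", "insufficient_data")
  q <- stats::quantile(day_tab$act, c(0.25, 0.75), names = FALSE)
  low_days <- day_tab$key[day_tab$act <= q[1]]
  high_days <- day_tab$key[day_tab$act >= q[2]]
  if (length(low_days) < 2 || length(high_days) < 2) {
    nl_stop("fewer than 2 days per quartile", "insufficient_data")
  }
  pool <- function(keys) {
    unlist(table$visit_speeds[day_key %in% keys], use.names = FALSE)
  }
  low <- pool(low_days); high <- pool(high_days)
  ht <- group_compare(low, high, test = "mwu", n_comparisons = n_comparisons)
  list(low_speeds = low, high_speeds = high, U = ht$statistic, p = ht$p,
       p_adjusted = ht$p_adjusted, low_days = low_days, high_days = high_days)
}

#' Two-group comparison with Bonferroni adjustment
#'
#' Two-sided Student's t (pooled variance) or Mann-Whitney U test with
#' `p_adjusted = min(1, p * n_comparisons)`.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param test `"t"` or `"mwu"`.
#' @param n_comparisons Bonferroni multiplicity.
#' @return list `statistic`, `p`, `p_adjusted`, `test`.
#' @export
group_compare <- function(values_a, values_b, test = c("t", "mwu"),
                          n_comparisons = 1) {
  test <- match.arg(test)
  nl_assert(length(values_a) >= 2 && length(values_b) >= 2,
            "each group needs >= 2 values")
  if (test == "t") {
    if (stats::sd(values_a) < 1e-12 && stats::sd(values_b) < 1e-12) {
      nl_stop("degenerate variance for the t-test; consider test = 'mwu'",
              "degenerate_variance")
    }
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    stat <- unname(ht$statistic)
  } else {
    exact <- length(values_a) <= 20 && length(values_b) <= 20 &&
      !any(duplicated(c(values_a, values_b)))
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = exact, correct = TRUE))
    stat <- unname(ht$statistic)
  }
  list(statistic = stat, p = ht$p.value,
       p_adjusted = min(1, ht$p.value * n_comparisons), test = test)
}

#' Per mouse-day coupling table from a synthetic dataset
#'
#' Collapses a [synth_multiday_experiment()] dataset to one row per
#' mouse-day with the slow-visit count, total visit count and the
#' ground-truth standardized NREM activity of the *preceding* day's rest —
#' the regression table for [recover_coupling()].  Motif labels come either
#' from the ground truth or from a 2-component speed-mixture classification
#' of the measured visit speeds.
#'
#' @param dataset output of [synth_multiday_experiment()].
#' @param use_true_labels use ground-truth motif labels (`TRUE`) or classify
#'   measured visit speeds with [fit_speed_mixture()].
#' @return data.frame `mouse`, `day`, `n_slow`, `n_visits`, `activity`
#'   (preceding-day standardized NREM amplitude); day-1 rows are excluded
#'   (no preceding sleep).
#' @export
coupling_table <- function(dataset, use_true_labels = TRUE) {
  gt <- dataset$ground_truth
  vis <- gt$visits
  if (is.null(vis) || !nrow(vis)) nl_stop("dataset contains no visits",
                                          "insufficient_data")
  if (use_true_labels) {
    vis$slow <- vis$motif == "slow"
  } else {
    speeds <- unlist(lapply(dataset$trials, function(tr) {
      v <- detect_port_entries(tr, attr(tr, "geometry"))
      v$visit_speed[!is.na(v$visit_speed)]
    }))
    mix <- fit_speed_mixture(speeds)
    boundary <- if (mix$selected_k == 2) mix$boundary else stats::median(speeds)
    vis$slow <- vis$target_speed < boundary
  }
  agg <- stats::aggregate(cbind(n_slow = vis$slow, n_visits = rep(1, nrow(vis))),
                          by = list(mouse = vis$mouse, day = vis$day), FUN = sum)
  act <- gt$nrem_activity
  agg$activity <- mapply(function(m, d) {
    v <- act$standardized[act$mouse == m & act$day == d - 1]
    if (length(v)) v else NA_real_
  }, agg$mouse, agg$day)
  agg <- agg[!is.na(agg$activity), ]
  rownames(agg) <- NULL
  agg
}

#' Estimate the planted sleep-to-behavior coupling
#'
#' Regresses the per mouse-day logit slow-visit fraction on the preceding
#' standardized NREM activity.  Fractions strictly inside (0, 1) use the
#' exact logit; boundary fractions use the empirical logit
#' `log((x + 0.5) / (n - x + 0.5))`.  A nonparametric bootstrap over
#' mouse-days gives the confidence interval.
#'
#' @param tbl a [coupling_table()] (columns `mouse`, `day`, `n_slow`,
#'   `n_visits`, `activity`; alternatively a `slow_fraction` column replaces
#'   the counts).
#' @param true_coupling optional planted value; enables the `bias` field.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list `estimate`, `ci` (length 2), `bias` (or `NA`), `n`.
#' @export
recover_coupling <- function(tbl, true_coupling = NA, n_boot = 200,
                             conf = 0.95, seed = 1L) {
  if (!nrow(tbl)) nl_stop("empty coupling table", "insufficient_data")
  y <- if ("slow_fraction" %in% names(tbl)) {
    fr <- tbl$slow_fraction
    n <- tbl$n_visits %||% rep(1e6, nrow(tbl))
    ifelse(fr > 0 & fr < 1, logit(fr),
           log((fr * n + 0.5) / (n - fr * n + 0.5)))
  } else {
    x <- tbl$n_slow; n <- tbl$n_visits
    ifelse(x > 0 & x < n, logit(x / n), log((x + 0.5) / (n - x + 0.5)))
  }
  fit_slope <- function(idx) {
    a <- tbl$activity[idx]
    if (stats::sd(a) < 1e-12) return(NA_real_)
    unname(stats::coef(stats::lm(y[idx] ~ a))[2])
  }
  est <- fit_slope(seq_len(nrow(tbl)))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fit_slope(sample.int(nrow(tbl), replace = TRUE))
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       bias = if (is.na(true_coupling)) NA_real_ else est - true_coupling,
       n = nrow(tbl))
}
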