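#' Normalize a bioluminescence track to its first measurement
#'
#' Each animal's longitudinal BLI series (total flux, photons/s) is divided
#' by its own first measurement, so growth curves are comparable across
#' animals regardless of initial engraftment size.
#'
#' @param track A list or one-animal tibble with `times` (days, strictly
#'   increasing) and `bli` (photons/s, same length, first value positive);
#'   optional `mouse_id`, `group`.
#' @return The track with a `normalized` element, `normalized[1] == 1`.
#' @export
normalize_track <- function(track) {
  t <- track$times
  b <- track$bli
  if (length(t) != length(b)) abort("times and bli must have equal length")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("measurement times must be strictly increasing")
  }
  if (any(b < 0)) abort("bioluminescence must be nonnegative")
  if (b[1] <= 0) {
    abort(paste0("cannot normalize: first measurement is zero for mouse ",
                 track$mouse_id %||% "<unnamed>"))
  }
  track$normalized <- b / b[1]
  track
}

#' Normalize a long table of BLI tracks
#'
#' @param tracks Tibble with columns `mouse_id`, `group`, `day`,
#'   `bli_photons_per_s`.
#' @return The tibble with a `normalized` column (per-animal ratio to that
#'   animal's first measurement).
#' @export
normalize_tracks <- function(tracks) {
  tracks <- as_tibble(tracks)
  if (nrow(tracks) == 0) abort("no tracks supplied")
  tracks |>
    group_by(.data$mouse_id) |>
    arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(\(d, key) {
      tr <- normalize_track(list(mouse_id = key$mouse_id[1], times = d$day,
                                 bli = d$bli_photons_per_s))
      mutate(d, normalized = tr$normalized)
    }) |>
    ungroup()
}

#' Per-group growth summaries of normalized BLI
#'
#' Mean and standard error of the normalized BLI per group and timepoint,
#' over the animals still measured at that timepoint (animals reaching
#' endpoint simply drop out of later means; their n is reported).
#'
#' @param tracks Long tibble with `mouse_id`, `group`, `day`,
#'   `bli_photons_per_s`; normalization is (re)computed internally.
#' @return Tibble with `group`, `day`, `n`, `mean_normalized`,
#'   `sem_normalized`.
#' @export
group_growth_summary <- function(tracks) {
  x <- normalize_tracks(tracks)
  x |>
    group_by(.data$group, .data$day) |>
    summarise(n = dplyr::n_distinct(.data$mouse_id),
              mean_normalized = mean(.data$normalized),
              sem_normalized = ifelse(n > 1,
                                      stats::sd(.data$normalized) / sqrt(n),
                                      0),
              .groups = "drop") |>
    arrange(.data$group, .data$day)
}

#' Baseline-balanced randomization into treatment groups
#'
#' Animals are sorted by baseline tumor signal (descending, ties broken by
#' a seeded shuffle) and dealt into groups in a serpentine pattern
#' (1..k, k..1, ...), which keeps group baseline means as close as that
#' scheme allows. Deterministic for a given seed.
#'
#' @param baseline Named numeric vector: baseline BLI per animal id.
#' @param k_groups Number of groups (>= 2).
#' @param seed Integer seed for tie-shuffling.
#' @return Tibble with `mouse_id`, `baseline`, `group` (factor
#'   `"G1".."Gk"`).
#' @export
randomize_balanced <- function(baseline, k_groups, seed = 1L) {
  if (k_groups < 2) abort("need at least 2 groups")
  if (is.null(names(baseline)) || any(names(baseline) == "")) {
    abort("baseline must be a named vector (names = animal ids)")
  }
  n <- length(baseline)
  if (n < k_groups) abort("fewer animals than groups")
  ord <- withr::with_seed(seed,
    order(-baseline, stats::runif(n)))
  pattern <- c(seq_len(k_groups), rev(seq_len(k_groups)))
  g <- pattern[(seq_len(n) - 1L) %% (2L * k_groups) + 1L]
  tibble(mouse_id = names(baseline)[ord],
         baseline = unname(baseline[ord]),
         group = factor(paste0("G", g),
                        levels = paste0("G", seq_len(k_groups))))
}

#' Kaplan-Meier survival curve and median
#'
#' Product-limit estimate of the survival function from time-to-event
#' records with right censoring, via `survival::survfit`. The median is
#' the smallest observed event time at which the estimate falls to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param records Tibble with `time_days` (> 0) and `event` (TRUE = death
#'   observed, FALSE = censored); optional `mouse_id`, `group`.
#' @return A list of class `km_curve`: `time` and `surv` (step function at
#'   event times), `n_risk`, `n_event`, `median`, and the underlying
#'   `survfit` object as `fit`.
#' @export
km_curve <- function(records) {
  r <- as_tibble(records)
  if (nrow(r) < 1) abort("need at least one survival record")
  if (any(r$time_days <= 0)) abort("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = r)
  ev <- fit$n.event > 0
  time <- fit$time[ev]
  surv <- fit$surv[ev]
  med <- if (any(surv <= 0.5 + 1e-12)) min(time[surv <= 0.5 + 1e-12]) else NA_real_
  structure(list(time = time, surv = surv,
                 n_risk = fit$n.risk[ev], n_event = fit$n.event[ev],
                 median = med, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", sum(x$n_event), "events;",
      if (is.na(x$median)) "median not reached"
      else paste("median", x$median, "days"), "\n")
  print(tibble(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
               surv = x$surv))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) two-sample log-rank test via `survival::survdiff`:
#' chi-square statistic on 1 df comparing observed with expected events
#' under the pooled hazard, p-value from the chi-square upper tail.
#'
#' @param group_a,group_b Tibbles of survival records (`time_days`,
#'   `event`).
#' @return A list with `statistic` (chi-square), `p_value`, and
#'   `observed_minus_expected` for group a.
#' @export
log_rank <- function(group_a, group_b) {
  a <- as_tibble(group_a)
  b <- as_tibble(group_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("both groups must be non-empty")
  if (sum(a$event) + sum(b$event) == 0) {
    abort("log-rank test undefined: no events in either group")
  }
  d <- bind_rows(mutate(a, .arm = "a"), mutate(b, .arm = "b"))
  sd_ <- survival::survdiff(survival::Surv(time_days, event) ~ .arm, data = d)
  stat <- unname(sd_$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed_minus_expected = unname(sd_$obs[1] - sd_$exp[1]))
}

#' Full preclinical endpoint analysis
#'
#' Convenience composition: per-group growth summaries from BLI tracks,
#' per-group Kaplan-Meier medians, and pairwise log-rank tests of every
#' treatment group against a reference group.
#'
#' @param tracks Long BLI tibble (`mouse_id`, `group`, `day`,
#'   `bli_photons_per_s`).
#' @param survival_records Tibble with `mouse_id`, `group`, `time_days`,
#'   `event`.
#' @param reference Group label used as comparator (default the first
#'   level encountered).
#' @return A list with `growth` (group x day summary), `km` (per-group
#'   tibble: group, n, events, median_days) and `log_rank` (per-comparison
#'   tibble: group, statistic, p_value).
#' @export
run_invivo_analysis <- function(tracks, survival_records, reference = NULL) {
  s <- as_tibble(survival_records)
  groups <- unique(s$group)
  reference <- reference %||% groups[1]
  if (!reference %in% groups) abort("reference group not present")
  km <- purrr::map_dfr(groups, \(g) {
    cc <- km_curve(filter(s, .data$group == g))
    tibble(group = g, n = sum(s$group == g),
           events = sum(s$event[s$group == g]), median_days = cc$median)
  })
  lr <- purrr::map_dfr(setdiff(groups, reference), \(g) {
    t <- log_rank(filter(s, .data$group == reference),
                  filter(s, .data$group == g))
    tibble(group = g, statistic = t$statistic, p_value = t$p_value)
  })
  list(growth = group_growth_summary(tracks), km = km, log_rank = lr)
}
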