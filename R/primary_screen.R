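#' Configuration for classification and hit calling
#'
#' Bundles the tunable thresholds of the primary screen:
#' \describe{
#'   \item{sd_multiplier}{The hit threshold is the library mean percent
#'     inhibition plus `sd_multiplier` standard deviations (default 3).}
#'   \item{cytotox_ratio_threshold}{A compound whose drug/vehicle
#'     monoculture signal ratio falls below this is called directly
#'     cytotoxic (default 0.7, i.e. a >30\% kill in monoculture).}
#'   \item{protection_tolerance}{A monoculture-cytotoxic compound whose
#'     co-culture signal stays within this fraction of the vehicle
#'     co-culture signal is called "protected" by the endothelial cells
#'     (default 0.15).}
#'   \item{degeneracy_guard}{Minimum plate trophic effect (vehicle
#'     co-culture / vehicle monoculture) for percent inhibition to be
#'     defined; below it the denominator is too close to zero
#'     (default 1.1).}
#' }
#'
#' @param sd_multiplier Positive number.
#' @param cytotox_ratio_threshold In (0, 1).
#' @param protection_tolerance In (0, 1).
#' @param degeneracy_guard Greater than 1.
#' @return A list of class `hit_call_config`.
#' @export
hit_call_config <- function(sd_multiplier = 3,
                            cytotox_ratio_threshold = 0.7,
                            protection_tolerance = 0.15,
                            degeneracy_guard = 1.1) {
  if (sd_multiplier <= 0) abort("sd_multiplier must be > 0")
  if (cytotox_ratio_threshold <= 0 || cytotox_ratio_threshold >= 1) {
    abort("cytotox_ratio_threshold must be in (0, 1)")
  }
  if (protection_tolerance <= 0 || protection_tolerance >= 1) {
    abort("protection_tolerance must be in (0, 1)")
  }
  if (degeneracy_guard <= 1) abort("degeneracy_guard must exceed 1")
  structure(list(sd_multiplier = sd_multiplier,
                 cytotox_ratio_threshold = cytotox_ratio_threshold,
                 protection_tolerance = protection_tolerance,
                 degeneracy_guard = degeneracy_guard),
            class = "hit_call_config")
}

#' Trophic effect of co-culture
#'
#' Fold increase in vehicle-treated tumor-cell signal caused by co-culture
#' with endothelial cells: the ratio of the vehicle co-culture mean to the
#' vehicle monoculture mean. In the U87/HBMEC system this is about 2-fold.
#'
#' @param co_vehicle_mean,mono_vehicle_mean Positive mean readouts
#'   (photons/s for bioluminescence).
#' @return Dimensionless fold.
#' @export
#' @examples
#' trophic_effect(2e6, 1e6) # 2-fold stimulation
trophic_effect <- function(co_vehicle_mean, mono_vehicle_mean) {
  if (any(co_vehicle_mean <= 0) || any(mono_vehicle_mean <= 0)) {
    abort("trophic_effect requires strictly positive vehicle means")
  }
  co_vehicle_mean / mono_vehicle_mean
}

#' Percent inhibition of the trophic effect
#'
#' The screen's primary statistic:
#' \deqn{100 \times \frac{A - B}{A - C}}
#' where A is the vehicle-treated co-culture mean, B the drug-treated
#' co-culture mean and C the vehicle-treated monoculture mean. 100 means
#' the compound fully abolishes the endothelial growth stimulus (drug
#' co-culture signal falls to the monoculture level) without implying any
#' direct kill; 0 means no effect on the stimulus. Values outside [0, 100]
#' are legitimate (over-suppression below monoculture level, or
#' enhancement) and are reported unclipped.
#'
#' The statistic is undefined when the plate's trophic effect A/C does not
#' exceed `degeneracy_guard`: the denominator is then dominated by noise.
#'
#' @param co_vehicle_mean,co_drug_mean,mono_vehicle_mean Mean readouts.
#' @param degeneracy_guard Minimum A/C ratio (default 1.1).
#' @return Percent inhibition (may be < 0 or > 100).
#' @export
#' @examples
#' percent_inhibition(2.0, 1.04, 1.0) # 96
#' percent_inhibition(2.0, 1.0, 1.0)  # 100, complete blockade
percent_inhibition <- function(co_vehicle_mean, co_drug_mean,
                               mono_vehicle_mean, degeneracy_guard = 1.1) {
  if (any(mono_vehicle_mean <= 0) || any(co_vehicle_mean <= 0)) {
    abort("vehicle means must be strictly positive")
  }
  te <- co_vehicle_mean / mono_vehicle_mean
  if (any(te <= degeneracy_guard)) {
    abort(paste0("percent inhibition undefined: trophic effect ",
                 paste(signif(te[te <= degeneracy_guard], 4), collapse = ", "),
                 " does not exceed the degeneracy guard ", degeneracy_guard))
  }
  100 * (co_vehicle_mean - co_drug_mean) /
    (co_vehicle_mean - mono_vehicle_mean)
}

#' Monoculture drug/vehicle signal ratio
#'
#' Operationalizes "direct cytotoxicity": a compound whose monoculture
#' signal under drug falls below `cytotox_ratio_threshold` times the vehicle
#' monoculture signal is considered directly cytotoxic to the tumor cells.
#'
#' @param mono_drug_mean,mono_vehicle_mean Mean readouts;
#'   `mono_vehicle_mean` must be positive.
#' @return Dimensionless ratio.
#' @export
mono_effect_ratio <- function(mono_drug_mean, mono_vehicle_mean) {
  if (any(mono_vehicle_mean <= 0)) {
    abort("mono_effect_ratio requires a positive vehicle mean")
  }
  mono_drug_mean / mono_vehicle_mean
}

#' Four-way compound classification
#'
#' Compounds in the co-culture screen fall into four behavioral classes:
#' \itemize{
#'   \item `PAN_CYTOTOXIC` — kills tumor cells in monoculture and in
#'     co-culture (mono ratio below the cytotoxicity threshold and
#'     co-culture signal depressed beyond `protection_tolerance`);
#'   \item `MONO_CYTOTOXIC_PROTECTED` — kills in monoculture but the
#'     co-cultured endothelial cells protect the tumor cells (co-culture
#'     signal within `protection_tolerance` of the vehicle co-culture);
#'   \item `ANTI_TROPHIC` — no direct kill, but percent inhibition of the
#'     trophic effect exceeds the library threshold;
#'   \item `INERT` — everything else.
#' }
#'
#' @param mono_ratio Monoculture drug/vehicle ratio.
#' @param co_drug_mean,co_vehicle_mean Co-culture means.
#' @param pct_inhibition Percent inhibition (NA when undefined; the
#'   classification then falls back on the monoculture criteria only).
#' @param library_threshold Library-wide percent-inhibition threshold
#'   (from [call_hits()]), above which a non-cytotoxic compound is
#'   ANTI_TROPHIC.
#' @param config A [hit_call_config()].
#' @return One of `"INERT"`, `"PAN_CYTOTOXIC"`,
#'   `"MONO_CYTOTOXIC_PROTECTED"`, `"ANTI_TROPHIC"` (vectorized).
#' @export
classify_compound <- function(mono_ratio, co_drug_mean, co_vehicle_mean,
                              pct_inhibition, library_threshold,
                              config = hit_call_config()) {
  cytotoxic <- mono_ratio < config$cytotox_ratio_threshold
  protected <- co_drug_mean >= co_vehicle_mean * (1 - config$protection_tolerance)
  anti <- !cytotoxic & !is.na(pct_inhibition) &
    pct_inhibition > library_threshold
  out <- rep("INERT", length(mono_ratio))
  out[cytotoxic & protected] <- "MONO_CYTOTOXIC_PROTECTED"
  out[cytotoxic & !protected] <- "PAN_CYTOTOXIC"
  out[anti] <- "ANTI_TROPHIC"
  out
}

#' Dual-criterion hit call over a screened library
#'
#' A hit must (i) show percent inhibition of the trophic effect strictly
#' greater than the library mean plus `sd_multiplier` standard deviations
#' (computed over every compound with a defined value, hits included, no
#' trimming) and (ii) show no direct cytotoxicity in monoculture.
#'
#' @param results A tibble with at least `compound_id`, `pct_inhibition`
#'   and `mono_effect_ratio` columns (e.g. from [run_primary_screen()]).
#' @param config A [hit_call_config()].
#' @return A list with `threshold_report` (one-row tibble: `n_defined`,
#'   `mean_pct`, `sd_pct`, `threshold`) and `calls` (per-compound tibble
#'   with `is_hit` and `margin` = pct_inhibition - threshold).
#' @export
call_hits <- function(results, config = hit_call_config()) {
  res <- as_tibble(results)
  defined <- !is.na(res$pct_inhibition)
  if (sum(defined) < 2) {
    abort("hit calling needs at least 2 compounds with defined percent inhibition")
  }
  mu <- mean(res$pct_inhibition[defined])
  sd_ <- stats::sd(res$pct_inhibition[defined])
  thr <- mu + config$sd_multiplier * sd_
  not_cytotoxic <- res$mono_effect_ratio >= config$cytotox_ratio_threshold
  is_hit <- defined & res$pct_inhibition > thr & not_cytotoxic
  list(
    threshold_report = tibble(n_defined = sum(defined), mean_pct = mu,
                              sd_pct = sd_, threshold = thr),
    calls = tibble(compound_id = res$compound_id,
                   pct_inhibition = res$pct_inhibition,
                   margin = res$pct_inhibition - thr,
                   is_hit = is_hit)
  )
}

# Per-plate vehicle means for the two physical-screen conditions.
plate_vehicle_means <- function(m) {
  m |>
    filter(.data$compound_id == VEHICLE,
           .data$condition %in% c("MONOCULTURE", "COCULTURE")) |>
    group_by(.data$plate_id, .data$condition) |>
    summarise(vehicle_mean = mean(.data$readout), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "vehicle_mean") |>
    dplyr::rename(mono_vehicle_mean = "MONOCULTURE",
                  co_vehicle_mean = "COCULTURE")
}

#' Run the full primary co-culture screen analysis
#'
#' For each compound, replicate wells (typically triplicates) are averaged
#' per condition; the plate's own vehicle wells provide the no-drug
#' baselines; the percent inhibition of the trophic effect, the monoculture
#' effect ratio and the four-way class are computed; and the library-wide
#' mean + k SD dual-criterion hit call is applied.
#'
#' @param measurements Well-measurement tibble (see [read_measurements()])
#'   with MONOCULTURE and COCULTURE wells.
#' @param compounds Optional compound annotation tibble; adds a `name`
#'   column to the output.
#' @param config A [hit_call_config()].
#' @return An object of class `primary_screen_result`: a list with
#'   `results` (per-compound tibble sorted by descending percent
#'   inhibition: compound_id, name, trophic_effect, mono_effect_ratio,
#'   pct_inhibition, category, is_hit, qc_flags), `hit_report` (threshold
#'   statistics) and `plate_vehicle` (per-plate vehicle means).
#' @export
run_primary_screen <- function(measurements, compounds = NULL,
                               config = hit_call_config()) {
  m <- validate_measurements(measurements)
  ctrl <- validate_plate_controls(m)
  if (!attr(ctrl, "pass")) {
    bad <- unique(ctrl$plate_id[!ctrl$ok])
    abort(paste0("plate(s) lacking vehicle controls: ",
                 paste(bad, collapse = ", ")))
  }
  veh <- plate_vehicle_means(m)

  per_compound <- m |>
    filter(.data$compound_id != VEHICLE,
           .data$condition %in% c("MONOCULTURE", "COCULTURE")) |>
    group_by(.data$plate_id, .data$compound_id, .data$condition) |>
    summarise(drug_mean = mean(.data$readout), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "drug_mean") |>
    dplyr::rename(mono_drug_mean = "MONOCULTURE", co_drug_mean = "COCULTURE") |>
    left_join(veh, by = "plate_id")

  if (any(is.na(per_compound$mono_drug_mean)) ||
      any(is.na(per_compound$co_drug_mean))) {
    bad <- per_compound$compound_id[is.na(per_compound$mono_drug_mean) |
                                      is.na(per_compound$co_drug_mean)]
    abort(paste0("compound(s) missing one screen arm: ",
                 paste(unique(bad), collapse = ", ")))
  }

  res <- per_compound |>
    mutate(
      trophic_effect = trophic_effect(.data$co_vehicle_mean,
                                      .data$mono_vehicle_mean),
      mono_effect_ratio = mono_effect_ratio(.data$mono_drug_mean,
                                            .data$mono_vehicle_mean),
      pct_defined = .data$trophic_effect > config$degeneracy_guard,
      pct_inhibition = ifelse(
        .data$pct_defined,
        100 * (.data$co_vehicle_mean - .data$co_drug_mean) /
          (.data$co_vehicle_mean - .data$mono_vehicle_mean),
        NA_real_)
    )

  hits <- call_hits(res, config)
  thr <- hits$threshold_report$threshold

  res <- res |>
    mutate(
      category = classify_compound(.data$mono_effect_ratio,
                                   .data$co_drug_mean,
                                   .data$co_vehicle_mean,
                                   .data$pct_inhibition, thr, config),
      is_hit = hits$calls$is_hit[match(.data$compound_id,
                                       hits$calls$compound_id)],
      qc_flags = qc_flag_string(
        undefined_pct = !.data$pct_defined,
        out_of_range = .data$pct_defined &
          (.data$pct_inhibition < 0 | .data$pct_inhibition > 100))
    )

  if (!is.null(compounds)) {
    res <- left_join(res, select(as_tibble(compounds), "compound_id", "name"),
                     by = "compound_id")
  } else {
    res$name <- NA_character_
  }

  res <- res |>
    select("compound_id", "name", "plate_id", "trophic_effect",
           "mono_effect_ratio", "pct_inhibition", "category", "is_hit",
           "qc_flags") |>
    arrange(dplyr::desc(.data$pct_inhibition))

  structure(list(results = res,
                 hit_report = hits$threshold_report,
                 plate_vehicle = veh),
            class = "primary_screen_result")
}

qc_flag_string <- function(...) {
  flags <- list(...)
  n <- length(flags[[1]])
  out <- character(n)
  for (nm in names(flags)) {
    out <- ifelse(flags[[nm]],
                  ifelse(out == "", nm, paste(out, nm, sep = ";")),
                  out)
  }
  out
}

#' @export
print.primary_screen_result <- function(x, ...) {
  cat("Primary co-culture screen:", nrow(x$results), "compounds on",
      nrow(x$plate_vehicle), "plate(s)\n")
  cat(sprintf("Library %%inhibition: mean %.2f, SD %.2f, hit threshold %.2f\n",
              x$hit_report$mean_pct, x$hit_report$sd_pct,
              x$hit_report$threshold))
  cat("Hits (anti-trophic, non-cytotoxic):", sum(x$results$is_hit), "\n")
  print(utils::head(x$results, 10))
  invisible(x)
}
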