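#' Subtract plate background from absorbance readouts
#'
#' Colorimetric viability readouts (absorbance at 490 nm) include a
#' medium + reagent background measured in dedicated BACKGROUND wells. Each
#' non-background readout has its plate's mean background subtracted;
#' results that would go negative are floored at 0 and flagged
#' `"sub_background_negative"`.
#'
#' @param raw Measurement tibble containing at least one BACKGROUND well
#'   per plate.
#' @return The corrected tibble (background wells removed) with a
#'   `qc_flags` column.
#' @export
subtract_background <- function(raw) {
  m <- as_tibble(raw)
  bg <- m |>
    filter(.data$condition == "BACKGROUND") |>
    group_by(.data$plate_id) |>
    summarise(background_mean = mean(.data$readout), .groups = "drop")
  plates <- unique(m$plate_id)
  missing <- setdiff(plates, bg$plate_id)
  if (length(missing) > 0) {
    abort(paste0("no background wells on plate(s): ",
                 paste(missing, collapse = ", ")))
  }
  m |>
    filter(.data$condition != "BACKGROUND") |>
    left_join(bg, by = "plate_id") |>
    mutate(corrected = .data$readout - .data$background_mean,
           qc_flags = ifelse(.data$corrected < 0,
                             "sub_background_negative", ""),
           readout = pmax(.data$corrected, 0)) |>
    select(-"corrected", -"background_mean")
}

#' Conditioned-media fold effect on growth
#'
#' Ratio of the vehicle-treated cell signal in endothelial conditioned
#' media (CM) to that in plain tumorsphere media (TSM): the trophic effect
#' carried by secreted factors. GBM lines show ~2-5 fold; normal astrocytes
#' only ~1.2 fold.
#'
#' @param cm_vehicle_mean,tsm_vehicle_mean Positive background-subtracted
#'   absorbance means at dose 0.
#' @return Dimensionless fold.
#' @export
cm_fold_effect <- function(cm_vehicle_mean, tsm_vehicle_mean) {
  if (any(cm_vehicle_mean <= 0) || any(tsm_vehicle_mean <= 0)) {
    abort("cm_fold_effect requires strictly positive vehicle means")
  }
  cm_vehicle_mean / tsm_vehicle_mean
}

#' Dose-wise CM/TSM normalized dose-response series
#'
#' At each dose, the mean background-subtracted CM signal is divided by the
#' mean signal in equivalently drug-treated TSM cultures, so direct drug
#' effects on the cells cancel and only the conditioned-media stimulus
#' remains. The dose-0 (vehicle) pair defines the CM fold effect. No curve
#' is fitted: the series is reported per dose.
#'
#' @param cm_wells,tsm_wells Measurement tibbles for one cell line x
#'   compound, background already subtracted; each dose must appear in both
#'   arms with at least 2 replicates.
#' @param cell_line,compound_id Optional labels carried into the output.
#' @return A tibble of class `dose_response_series`, ordered by dose, with
#'   columns `cell_line`, `compound_id`, `dose_uM`, `response_cm`,
#'   `response_tsm`, `normalized_response`, `sem` (delta-method SE of the
#'   ratio) and `cm_fold` (repeated; the dose-0 ratio).
#' @export
normalized_dose_response <- function(cm_wells, tsm_wells,
                                     cell_line = NA_character_,
                                     compound_id = NA_character_) {
  agg <- function(w, nm) {
    as_tibble(w) |>
      group_by(.data$dose_uM) |>
      summarise(mean = mean(.data$readout),
                sem = stats::sd(.data$readout) / sqrt(n()),
                n = n(), .groups = "drop") |>
      dplyr::rename_with(\(x) paste0(nm, "_", x), !"dose_uM")
  }
  cm <- agg(cm_wells, "cm")
  tsm <- agg(tsm_wells, "tsm")
  only_cm <- setdiff(cm$dose_uM, tsm$dose_uM)
  only_tsm <- setdiff(tsm$dose_uM, cm$dose_uM)
  if (length(only_cm) > 0 || length(only_tsm) > 0) {
    abort(paste0("doses present in one arm only: ",
                 paste(sort(c(only_cm, only_tsm)), collapse = ", ")))
  }
  x <- left_join(cm, tsm, by = "dose_uM") |> arrange(.data$dose_uM)
  if (any(x$cm_n < 2) || any(x$tsm_n < 2)) {
    abort("each dose needs at least 2 replicates in both arms")
  }
  if (!any(x$dose_uM == 0)) abort("a dose-0 (vehicle) pair is required")
  if (any(x$tsm_mean <= 0)) {
    abort(paste0("nonpositive TSM mean at dose(s): ",
                 paste(x$dose_uM[x$tsm_mean <= 0], collapse = ", ")))
  }
  ratio <- x$cm_mean / x$tsm_mean
  sem <- ratio * sqrt((x$cm_sem / x$cm_mean)^2 + (x$tsm_sem / x$tsm_mean)^2)
  out <- tibble(cell_line = cell_line, compound_id = compound_id,
                dose_uM = x$dose_uM,
                response_cm = x$cm_mean, response_tsm = x$tsm_mean,
                normalized_response = ratio, sem = sem,
                cm_fold = ratio[x$dose_uM == 0])
  class(out) <- c("dose_response_series", class(out))
  out
}

#' Percent inhibition of the conditioned-media trophic effect at a dose
#'
#' Same construct as the primary-screen statistic, applied to CM assays:
#' \deqn{100 \times \frac{F - R(d)}{F - 1}}
#' with F the vehicle CM fold and R(d) the CM/TSM normalized response at
#' dose d. 100 means the drug pulls the CM-stimulated signal all the way
#' down to the TSM level.
#'
#' @param series A [normalized_dose_response()] series.
#' @param dose Dose in the series (micromolar).
#' @param degeneracy_guard Minimum CM fold for the statistic to be defined.
#' @return Percent inhibition at that dose.
#' @export
anti_trophic_inhibition_at_dose <- function(series, dose,
                                            degeneracy_guard = 1.1) {
  if (!dose %in% series$dose_uM) {
    abort(paste0("dose ", dose, " not present in the series"))
  }
  f <- series$cm_fold[1]
  if (f <= degeneracy_guard) {
    abort(paste0("inhibition undefined: cm_fold ", signif(f, 4),
                 " does not exceed the degeneracy guard ", degeneracy_guard))
  }
  r <- series$normalized_response[series$dose_uM == dose]
  100 * (f - r) / (f - 1)
}

#' Responder classification for a dose series
#'
#' A cell line x compound series is RESPONSIVE when its maximal
#' anti-trophic inhibition over the tested (nonzero) doses reaches
#' `min_max_inhibition` percent, NON_RESPONSIVE otherwise (boundary counts
#' as responsive). Operationalizes the qualitative distinction between
#' lines whose CM stimulus is blocked by a drug and lines that are
#' completely unresponsive.
#'
#' @param series A [normalized_dose_response()] series with >= 3 doses.
#' @param min_max_inhibition Percent threshold, default 50.
#' @param degeneracy_guard Passed to [anti_trophic_inhibition_at_dose()].
#' @return `"RESPONSIVE"` or `"NON_RESPONSIVE"`.
#' @export
classify_responder <- function(series, min_max_inhibition = 50,
                               degeneracy_guard = 1.1) {
  doses <- series$dose_uM[series$dose_uM > 0]
  if (length(doses) < 3) abort("responder calls need at least 3 doses")
  inh <- vapply(doses, \(d)
                anti_trophic_inhibition_at_dose(series, d, degeneracy_guard),
                numeric(1))
  if (max(inh) >= min_max_inhibition) "RESPONSIVE" else "NON_RESPONSIVE"
}

#' Signed percent change of a readout relative to vehicle
#'
#' Direct drug effect on a cell population (e.g. endothelial cells or
#' astrocytes in monoculture): 100 x (drug - vehicle) / vehicle.
#'
#' @param drug_mean,vehicle_mean Mean readouts; `vehicle_mean` positive.
#' @return Signed percent (negative = fewer cells under drug).
#' @export
#' @examples
#' direct_effect_percent(0.65, 1.0) # -35: a 35% reduction
direct_effect_percent <- function(drug_mean, vehicle_mean) {
  if (any(vehicle_mean <= 0)) {
    abort("direct_effect_percent requires a positive vehicle mean")
  }
  100 * (drug_mean - vehicle_mean) / vehicle_mean
}

#' Run the secondary conditioned-media screen analysis
#'
#' Subtracts background, builds one normalized dose-response series per
#' cell line x compound, computes per-dose inhibition and the responder
#' call, and returns one long tidy table.
#'
#' @param measurements Absorbance measurement tibble with CM, TSM and
#'   BACKGROUND wells; a `cell_line` column is required.
#' @param responder_threshold Percent, default 50.
#' @param degeneracy_guard Minimum CM fold for inhibition to be defined.
#' @return A tibble with columns `cell_line`, `compound_id`, `dose_uM`,
#'   `response_cm`, `response_tsm`, `normalized_response`,
#'   `inhibition_pct`, `cm_fold`, `responder_call`.
#' @export
run_secondary_screen <- function(measurements, responder_threshold = 50,
                                 degeneracy_guard = 1.1) {
  m <- as_tibble(measurements)
  if (!"cell_line" %in% names(m)) abort("measurements need a cell_line column")
  corr <- subtract_background(m)
  combos <- corr |>
    filter(.data$compound_id != VEHICLE) |>
    distinct(.data$cell_line, .data$compound_id)
  purrr::pmap_dfr(combos, function(cell_line, compound_id) {
    sub <- filter(corr, .data$cell_line == !!cell_line)
    pick <- function(cond) {
      filter(sub, .data$condition == cond,
             .data$compound_id %in% c(!!compound_id, VEHICLE))
    }
    ser <- normalized_dose_response(pick("CM"), pick("TSM"),
                                    cell_line = cell_line,
                                    compound_id = compound_id)
    inh <- rep(NA_real_, nrow(ser))
    if (ser$cm_fold[1] > degeneracy_guard) {
      inh <- vapply(ser$dose_uM,
                    \(d) anti_trophic_inhibition_at_dose(ser, d,
                                                         degeneracy_guard),
                    numeric(1))
    }
    call <- tryCatch(
      classify_responder(ser, responder_threshold, degeneracy_guard),
      error = function(e) NA_character_)
    mutate(as_tibble(ser), inhibition_pct = inh, responder_call = call) |>
      select("cell_line", "compound_id", "dose_uM", "response_cm",
             "response_tsm", "normalized_response", "inhibition_pct",
             "cm_fold", "responder_call")
  })
}
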