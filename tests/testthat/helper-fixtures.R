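# Small in-code fixtures shared across test files.

# One row per well, long format, BLI by default.
make_wells <- function(plate_id, condition, compound_id, readout,
                       dose_uM = ifelse(compound_id == VEHICLE, 0, 5),
                       replicate = NULL, readout_kind = "BLI",
                       start_well = 0L) {
  n <- length(readout)
  if (is.null(replicate)) replicate <- seq_len(n)
  ix <- (start_well + seq_len(n) - 1L) %% 96L  # positions recycle; tests
                                               # never rely on uniqueness
  tibble::tibble(
    plate_id = plate_id, well_id = make_well_id(ix %/% 12L, ix %% 12L),
    condition = condition, compound_id = compound_id, dose_uM = dose_uM,
    replicate = replicate, readout = readout, readout_kind = readout_kind)
}

# Single-plate, zero-noise primary-screen fixture: per compound, supply the
# triplicate-constant mono-drug and co-drug means; vehicle wells at
# mono_vehicle / co_vehicle.
make_primary_fixture <- function(compounds, mono_drug, co_drug,
                                 mono_vehicle = 1.0, co_vehicle = 2.0,
                                 plate_id = "P01") {
  stopifnot(length(compounds) == length(mono_drug),
            length(compounds) == length(co_drug))
  rows <- list(
    make_wells(plate_id, "MONOCULTURE", VEHICLE, rep(mono_vehicle, 3),
               start_well = 0L),
    make_wells(plate_id, "COCULTURE", VEHICLE, rep(co_vehicle, 3),
               start_well = 3L)
  )
  w <- 6L
  for (i in seq_along(compounds)) {
    rows <- c(rows, list(
      make_wells(plate_id, "MONOCULTURE", compounds[i], rep(mono_drug[i], 3),
                 start_well = w),
      make_wells(plate_id, "COCULTURE", compounds[i], rep(co_drug[i], 3),
                 start_well = w + 3L)))
    w <- w + 6L
  }
  dplyr::bind_rows(rows)
}

# Zero-noise CM/TSM wells for a dose ladder, given per-dose expected means.
make_cm_tsm_wells <- function(doses, cm_means, tsm_means, reps = 3L,
                              plate_id = "S1") {
  grid <- tidyr::expand_grid(d = seq_along(doses), r = seq_len(reps))
  cm <- tibble::tibble(
    plate_id = plate_id, well_id = make_well_id(0L, 0L),
    condition = "CM",
    compound_id = ifelse(doses[grid$d] == 0, VEHICLE, "DRUG"),
    dose_uM = doses[grid$d], replicate = grid$r,
    readout = cm_means[grid$d], readout_kind = "ABSORBANCE")
  tsm <- dplyr::mutate(cm, condition = "TSM",
                       readout = tsm_means[grid$d])
  list(cm = cm, tsm = tsm)
}

# Hand product-limit estimator for uncensored/censored records; independent
# of the package's km_curve implementation.
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event]))
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  list(time = ut, surv = out)
}
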