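#' Configuration of the primary-screen simulator
#'
#' All planted parameters for a synthetic co-culture library screen. The
#' defaults reproduce the assay conditions of the screen the package
#' analyzes: a ~2-fold endothelial trophic effect on a 1e6 photons/s
#' monoculture baseline, a 2000-compound library screened at 5 micromolar
#' in triplicate, multiplicative lognormal well noise at CV 0.15, 80
#' compounds per plate with 24 vehicle wells per condition per plate, and
#' a class mix in which most compounds are inert, 2\% are pan-cytotoxic,
#' 2\% are monoculture-cytotoxic but protected in co-culture, and 0.5\%
#' (10 of 2000) are genuinely anti-trophic.
#'
#' @param seed Integer seed.
#' @param trophic_fold Planted vehicle co/mono fold (default 2.0).
#' @param mono_baseline Monoculture vehicle signal, photons/s.
#' @param noise_cv Lognormal coefficient of variation per well.
#' @param n_compounds Library size.
#' @param class_mix Named proportions over INERT, PAN_CYTOTOXIC,
#'   MONO_CYTOTOXIC_PROTECTED, ANTI_TROPHIC; must sum to 1. Planted class
#'   counts are derived deterministically from the proportions
#'   (largest-remainder rounding) and shuffled over compound ids, so the
#'   default 0.005 anti-trophic share of a 2000-compound library plants
#'   exactly 10 true hits.
#' @param anti_trophic_inhibition_range Planted inhibition fraction range
#'   for anti-trophic compounds (default 0.8-1.0, the span of the screen's
#'   prioritized candidates).
#' @param cytotoxic_multiplier_range Planted surviving-fraction range for
#'   cytotoxic compounds (default 0.2-0.45).
#' @param screen_dose_uM Library screening dose.
#' @param replicates Wells per compound per condition.
#' @param compounds_per_plate Compounds per logical plate.
#' @param vehicle_wells_per_condition Vehicle wells per condition per
#'   plate (default 24).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              trophic_fold = 2.0,
                              mono_baseline = 1.0e6,
                              noise_cv = 0.15,
                              n_compounds = 2000L,
                              class_mix = c(INERT = 0.955,
                                            PAN_CYTOTOXIC = 0.02,
                                            MONO_CYTOTOXIC_PROTECTED = 0.02,
                                            ANTI_TROPHIC = 0.005),
                              anti_trophic_inhibition_range = c(0.8, 1.0),
                              cytotoxic_multiplier_range = c(0.2, 0.45),
                              screen_dose_uM = 5,
                              replicates = 3L,
                              compounds_per_plate = 80L,
                              vehicle_wells_per_condition = 24L) {
  need <- c("INERT", "PAN_CYTOTOXIC", "MONO_CYTOTOXIC_PROTECTED",
            "ANTI_TROPHIC")
  if (!setequal(names(class_mix), need)) {
    abort("class_mix must name exactly the four compound classes")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) abort("class_mix must sum to 1")
  if (noise_cv < 0) abort("noise_cv must be nonnegative")
  if (trophic_fold <= 0) abort("trophic_fold must be positive")
  structure(as.list(environment()), class = "simulation_config")
}

# lognormal multiplier with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a primary co-culture library screen
#'
#' Emits a long well-measurement table (monoculture and co-culture arms,
#' triplicate compound wells at the screening dose plus per-plate vehicle
#' wells) together with the planted ground truth. Expected signals:
#' monoculture = baseline x mono_multiplier; co-culture = (baseline +
#' (trophic_fold - 1) x baseline x (1 - inhibition)) x co_multiplier.
#' Inert compounds have all multipliers 1; pan-cytotoxic compounds share a
#' kill multiplier in both arms; protected compounds are killed in
#' monoculture only; anti-trophic compounds act solely on the trophic
#' increment. Every well readout carries multiplicative lognormal noise.
#'
#' @param config A [simulation_config()].
#' @param drop_vehicle_plates Optional character vector of plate ids whose
#'   vehicle wells are withheld (to plant a QC defect).
#' @return A list with `measurements`, `compounds` (annotation table) and
#'   `ground_truth` (per-compound planted class and multipliers).
#' @export
simulate_primary_library <- function(config = simulation_config(),
                                     drop_vehicle_plates = character()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_compounds
    # deterministic class counts (largest-remainder rounding of the mix),
    # shuffled over compound ids: a 0.005 share of 2000 plants exactly 10
    counts <- diff(c(0L, round(cumsum(cfg$class_mix) * n)))
    classes <- sample(rep(names(cfg$class_mix), times = counts))
    kill <- stats::runif(n, cfg$cytotoxic_multiplier_range[1],
                         cfg$cytotoxic_multiplier_range[2])
    inhib <- stats::runif(n, cfg$anti_trophic_inhibition_range[1],
                          cfg$anti_trophic_inhibition_range[2])
    mono_mult <- ifelse(classes %in% c("PAN_CYTOTOXIC",
                                       "MONO_CYTOTOXIC_PROTECTED"), kill, 1)
    co_mult <- ifelse(classes == "PAN_CYTOTOXIC", kill, 1)
    inhibition <- ifelse(classes == "ANTI_TROPHIC", inhib, 0)

    ids <- sprintf("CPD%04d", seq_len(n))
    plate_ix <- (seq_len(n) - 1L) %/% cfg$compounds_per_plate + 1L
    plate_id <- sprintf("P%02d", plate_ix)
    pos <- (seq_len(n) - 1L) %% cfg$compounds_per_plate
    well <- make_well_id(pos %/% 12L, pos %% 12L)

    truth <- tibble(compound_id = ids, plate_id = plate_id, class = classes,
                    mono_multiplier = mono_mult, co_multiplier = co_mult,
                    inhibition_fraction = inhibition)

    b <- cfg$mono_baseline
    mono_expect <- b * mono_mult
    co_expect <- (b + (cfg$trophic_fold - 1) * b * (1 - inhibition)) * co_mult

    reps <- cfg$replicates
    cmpd <- tibble(
      plate_id = rep(plate_id, each = 2L * reps),
      well_id = rep(well, each = 2L * reps),
      condition = rep(rep(c("MONOCULTURE", "COCULTURE"), each = reps), n),
      compound_id = rep(ids, each = 2L * reps),
      dose_uM = cfg$screen_dose_uM,
      replicate = rep(rep(seq_len(reps), times = 2L), n),
      expected = as.vector(t(cbind(
        matrix(rep(mono_expect, reps), ncol = reps),
        matrix(rep(co_expect, reps), ncol = reps))))
    )

    n_plates <- max(plate_ix)
    vwell_pos <- cfg$compounds_per_plate +
      seq_len(ceiling(cfg$vehicle_wells_per_condition / cfg$replicates)) - 1L
    nv <- cfg$vehicle_wells_per_condition
    veh <- tidyr::expand_grid(
      plate_id = sprintf("P%02d", seq_len(n_plates)),
      condition = c("MONOCULTURE", "COCULTURE"),
      slot = seq_len(nv)
    ) |>
      mutate(
        well_id = make_well_id((vwell_pos[(.data$slot - 1L) %/%
                                            cfg$replicates + 1L]) %/% 12L,
                               (vwell_pos[(.data$slot - 1L) %/%
                                            cfg$replicates + 1L]) %% 12L),
        compound_id = VEHICLE, dose_uM = 0,
        replicate = (.data$slot - 1L) %% cfg$replicates + 1L,
        expected = ifelse(.data$condition == "MONOCULTURE",
                          b, b * cfg$trophic_fold)
      ) |>
      select(-"slot")

    meas <- bind_rows(cmpd, veh) |>
      mutate(readout = .data$expected * rlnorm_cv(n(), cfg$noise_cv),
             readout_kind = "BLI") |>
      select(all_of(MEASUREMENT_COLS)) |>
      filter(!(.data$plate_id %in% drop_vehicle_plates &
                 .data$compound_id == VEHICLE))

    compounds <- tibble(compound_id = ids, name = ids,
                        annotation = paste0("synthetic ", classes),
                        screen_dose_uM = cfg$screen_dose_uM)

    list(measurements = meas, compounds = compounds, ground_truth = truth)
  })
}

#' Configuration of the conditioned-media dose-response simulator
#'
#' Defaults emulate the secondary screen: a five-point dose ladder from
#' 0.05 to 500 micromolar, a 2-fold conditioned-media stimulus for
#' GBM-like lines (use `cm_fold = 1.2` for astrocyte-like lines), a Hill
#' inhibition model for the drug's action on the trophic increment, and
#' absorbance readouts (baseline 1.0, planted background 0.08) with
#' lognormal noise at CV 0.1.
#'
#' @param cell_line Label.
#' @param doses Micromolar dose ladder (0 = vehicle is added
#'   automatically).
#' @param cm_fold Planted vehicle CM/TSM fold.
#' @param i_max Maximal inhibition fraction (0-1) of the trophic
#'   increment.
#' @param ec50 Dose of half-maximal inhibition, micromolar.
#' @param hill Hill coefficient.
#' @param baseline_absorbance TSM vehicle signal (background-subtracted
#'   scale).
#' @param background Planted background absorbance.
#' @param noise_cv Lognormal CV per well.
#' @param replicates Wells per dose per arm.
#' @param n_background_wells Background wells per plate.
#' @return A list of class `dose_sim_config`.
#' @export
dose_sim_config <- function(cell_line = "GBM1",
                            doses = c(0.05, 0.5, 5, 50, 500),
                            cm_fold = 2.0,
                            i_max = 1.0,
                            ec50 = 5,
                            hill = 1,
                            baseline_absorbance = 1.0,
                            background = 0.08,
                            noise_cv = 0.1,
                            replicates = 3L,
                            n_background_wells = 4L) {
  if (i_max < 0 || i_max > 1) abort("i_max must be in [0, 1]")
  if (ec50 <= 0) abort("ec50 must be positive")
  if (cm_fold <= 0) abort("cm_fold must be positive")
  if (any(doses <= 0)) abort("doses must be positive (0 is added as vehicle)")
  structure(as.list(environment()), class = "dose_sim_config")
}

# Hill inhibition of the trophic increment
hill_inhibition <- function(d, i_max, ec50, hill) {
  ifelse(d == 0, 0, i_max * d^hill / (ec50^hill + d^hill))
}

#' Simulate a CM/TSM dose-response assay
#'
#' TSM wells sit at the baseline absorbance regardless of dose (the
#' CM/TSM normalization exists precisely to cancel direct drug effects, so
#' none are planted); CM wells at dose d sit at
#' baseline x (1 + (cm_fold - 1) x (1 - inhibition(d))) with Hill-model
#' inhibition. Background wells carry the planted offset. All wells get
#' multiplicative lognormal noise, and the background offset is added to
#' every non-background well so that background subtraction is a real step.
#'
#' @param config A [dose_sim_config()].
#' @param seed Integer seed.
#' @param compound_id Label for drug wells.
#' @return A list with `measurements` (CM, TSM and BACKGROUND wells,
#'   absorbance) and `ground_truth` (per-dose planted normalized response).
#' @export
simulate_dose_response <- function(config = dose_sim_config(), seed = 1L,
                                   compound_id = "DRUG1") {
  cfg <- config
  withr::with_seed(seed, {
    doses <- c(0, sort(cfg$doses))
    inh <- hill_inhibition(doses, cfg$i_max, cfg$ec50, cfg$hill)
    tsm_expect <- rep(cfg$baseline_absorbance, length(doses))
    cm_expect <- cfg$baseline_absorbance *
      (1 + (cfg$cm_fold - 1) * (1 - inh))
    grid <- tidyr::expand_grid(dose_ix = seq_along(doses),
                               condition = c("TSM", "CM"),
                               replicate = seq_len(cfg$replicates))
    plate <- paste0("S-", cfg$cell_line)
    wells <- grid |>
      mutate(dose_uM = doses[.data$dose_ix],
             expected = ifelse(.data$condition == "CM",
                               cm_expect[.data$dose_ix],
                               tsm_expect[.data$dose_ix]),
             plate_id = plate,
             compound_id = ifelse(.data$dose_uM == 0, VEHICLE, compound_id),
             readout = (.data$expected + cfg$background) *
               rlnorm_cv(n(), cfg$noise_cv),
             readout_kind = "ABSORBANCE")
    nr <- nrow(wells)
    wells$well_id <- make_well_id((seq_len(nr) - 1L) %/% 12L,
                                  (seq_len(nr) - 1L) %% 12L)
    bg <- tibble(plate_id = plate,
                 well_id = make_well_id(7L, 12L - seq_len(cfg$n_background_wells)),
                 condition = "BACKGROUND", compound_id = NA_character_,
                 dose_uM = 0, replicate = seq_len(cfg$n_background_wells),
                 readout = cfg$background *
                   rlnorm_cv(cfg$n_background_wells, cfg$noise_cv),
                 readout_kind = "ABSORBANCE")
    meas <- bind_rows(select(wells, all_of(MEASUREMENT_COLS)), bg) |>
      mutate(cell_line = cfg$cell_line)
    truth <- tibble(cell_line = cfg$cell_line, compound_id = compound_id,
                    dose_uM = doses, inhibition_fraction = inh,
                    expected_normalized = cm_expect / tsm_expect,
                    cm_fold = cfg$cm_fold)
    list(measurements = meas, ground_truth = truth)
  })
}

#' Astrocyte-like dose-response configuration
#'
#' Convenience preset: normal-human-astrocyte-like line with the small
#' planted conditioned-media stimulus (1.2-fold) and no drug response.
#'
#' @param ... Overrides passed to [dose_sim_config()].
#' @return A `dose_sim_config`.
#' @export
astrocyte_dose_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(cell_line = "NHA", cm_fold = 1.2, i_max = 0)
  do.call(dose_sim_config, utils::modifyList(defaults, args))
}

#' Simulate a direct-effect monoculture assay
#'
#' Vehicle wells at a fixed mean and drug wells at
#' vehicle x (1 + effect_percent/100), both with lognormal noise. The
#' default effect is the planted -35\% endothelial-cell reduction used for
#' the triacetylated-resveratrol-like scenario; positive values model
#' proliferation increases.
#'
#' @param effect_percent Signed percent change under drug (> -100).
#' @param n_wells Wells per arm.
#' @param noise_cv Lognormal CV.
#' @param seed Integer seed.
#' @param vehicle_mean Vehicle readout mean.
#' @param cell_line,compound_id Labels.
#' @return Measurement tibble (MONOCULTURE wells, vehicle and drug).
#' @export
simulate_direct_effect <- function(effect_percent = -35, n_wells = 6L,
                                   noise_cv = 0.1, seed = 1L,
                                   vehicle_mean = 1.0,
                                   cell_line = "HBMEC",
                                   compound_id = "TAR") {
  if (effect_percent <= -100) abort("effect_percent must exceed -100")
  withr::with_seed(seed, {
    expected <- c(rep(vehicle_mean, n_wells),
                  rep(vehicle_mean * (1 + effect_percent / 100), n_wells))
    tibble(
      plate_id = paste0("D-", cell_line),
      well_id = make_well_id((seq_len(2L * n_wells) - 1L) %/% 12L,
                             (seq_len(2L * n_wells) - 1L) %% 12L),
      condition = "MONOCULTURE",
      compound_id = rep(c(VEHICLE, compound_id), each = n_wells),
      dose_uM = rep(c(0, 5), each = n_wells),
      replicate = rep(seq_len(n_wells), times = 2L),
      readout = expected * rlnorm_cv(2L * n_wells, noise_cv),
      readout_kind = "ABSORBANCE",
      cell_line = cell_line
    )
  })
}

#' Configuration of the xenograft cohort simulator
#'
#' Intracranial tumor burden grows exponentially,
#' BLI(t) = baseline x exp(rate x t); each animal draws its own rate as a
#' lognormal multiple of its group rate (CV `rate_cv`, the biological
#' heterogeneity), measurements carry lognormal noise at `noise_cv`, and
#' death occurs at the first crossing of `burden_threshold` by the latent
#' signal. Default group rates place the vehicle median endpoint at day 15
#' and the treated median at day 22 (rate ratio ~0.68), matching a
#' treatment that roughly halves net growth over the study window.
#'
#' @param n_per_group Animals per group (default 6).
#' @param baseline_bli Photons/s at first imaging.
#' @param growth_rates Named per-day rates, one per group.
#' @param burden_threshold Photons/s at which the animal reaches endpoint.
#' @param measurement_days Imaging schedule (days post-implantation).
#' @param noise_cv Measurement lognormal CV.
#' @param rate_cv Between-animal lognormal CV on the growth rate.
#' @param study_end Day at which survivors are censored.
#' @return A list of class `xeno_sim_config`.
#' @export
xeno_sim_config <- function(n_per_group = 6L,
                            baseline_bli = 1e6,
                            growth_rates = c(vehicle = log(1000) / 15,
                                             treated = log(1000) / 22),
                            burden_threshold = 1e9,
                            measurement_days = seq(0, 42, by = 7),
                            noise_cv = 0.15,
                            rate_cv = 0.15,
                            study_end = 60) {
  if (is.null(names(growth_rates))) abort("growth_rates must be named by group")
  if (growth_rates[1] <= 0) abort("the first (vehicle) growth rate must be positive")
  if (burden_threshold <= baseline_bli) {
    abort("burden_threshold must exceed baseline_bli")
  }
  structure(as.list(environment()), class = "xeno_sim_config")
}

#' Simulate a xenograft cohort: BLI tracks and survival records
#'
#' Each animal's latent signal is baseline x exp(rate_i x t); its event
#' time is the continuous threshold-crossing time
#' log(threshold/baseline)/rate_i, censored at `study_end` if not reached.
#' Measured BLI is the latent signal with lognormal noise, reported on the
#' imaging schedule and truncated at death.
#'
#' @param config A [xeno_sim_config()].
#' @param seed Integer seed.
#' @return A list with `tracks` (`mouse_id`, `group`, `day`,
#'   `bli_photons_per_s`), `survival` (`mouse_id`, `group`, `time_days`,
#'   `event`) and `ground_truth` (per-animal rate and crossing time).
#' @export
simulate_xenograft_cohort <- function(config = xeno_sim_config(), seed = 1L) {
  cfg <- config
  withr::with_seed(seed, {
    groups <- names(cfg$growth_rates)
    ids <- unlist(lapply(groups, \(g) paste0(g, "_", seq_len(cfg$n_per_group))))
    grp <- rep(groups, each = cfg$n_per_group)
    rate <- unname(cfg$growth_rates[grp]) *
      rlnorm_cv(length(ids), cfg$rate_cv)
    cross <- log(cfg$burden_threshold / cfg$baseline_bli) / rate
    event <- cross <= cfg$study_end
    time <- ifelse(event, cross, cfg$study_end)
    truth <- tibble(mouse_id = ids, group = grp, rate = unname(rate),
                    crossing_day = unname(cross))
    survival <- tibble(mouse_id = ids, group = grp,
                       time_days = unname(time), event = event)
    tracks <- tidyr::expand_grid(ix = seq_along(ids),
                                 day = cfg$measurement_days) |>
      mutate(mouse_id = ids[.data$ix], group = grp[.data$ix],
             latent = cfg$baseline_bli * exp(rate[.data$ix] * .data$day)) |>
      filter(.data$day <= time[.data$ix]) |>
      mutate(bli_photons_per_s = .data$latent * rlnorm_cv(n(), cfg$noise_cv)) |>
      select("mouse_id", "group", "day", "bli_photons_per_s")
    list(tracks = tracks, survival = survival, ground_truth = truth)
  })
}

#' Weibull fallback generator for survival-only experiments
#'
#' Direct parametric event times for tests that need survival records
#' without the growth model (e.g. log-rank calibration).
#'
#' @param n Number of animals.
#' @param shape,scale Weibull parameters (shape 1 = exponential).
#' @param censor_time Optional administrative censoring time.
#' @param group Group label.
#' @param seed Integer seed.
#' @return A survival-record tibble.
#' @export
simulate_survival_times <- function(n, shape = 1, scale = 20,
                                    censor_time = Inf, group = "G1",
                                    seed = 1L) {
  withr::with_seed(seed, {
    t <- stats::rweibull(n, shape = shape, scale = scale)
    tibble(mouse_id = paste0(group, "_", seq_len(n)), group = group,
           time_days = pmin(t, censor_time), event = t <= censor_time)
  })
}
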