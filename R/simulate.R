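#' Default simulation configuration
#'
#' Parameters of the coupled synthetic-data generator. The defaults emulate
#' a cool-temperate winter campaign: an hourly temperature record from
#' September 1 to April 30 with seasonal and diurnal cycles plus AR(1)
#' weather noise; weekly bud sampling at 28 timepoints from September 20
#' for two cultivars with 3 biological x 2 technical qPCR replicates; a
#' chill-portion threshold per cultivar that fixes the true
#' endodormancy-to-ecodormancy transition (72.9 and 83.9 CP, the early and
#' late cultivar) and a growing-degree-hour threshold of 2750 GDH for bud
#' break; and a candidate-gene panel of 36 trajectory genes drawn from six
#' expression-pattern archetypes, 4 temperature-coupled genes, 3 stable
#' reference genes and 2 silent genes.
#'
#' @param seed integer master seed; every stochastic element of the
#'   generator derives from it.
#' @return Nested list of class `sim_config`.
#' @export
default_sim_config <- function(seed = 1) {
  structure(list(
    season_start = as.Date("2017-09-01"),
    season_end = as.Date("2018-04-30"),
    temperature = list(
      annual_mean = 9.5,        # degC
      seasonal_amplitude = 9.5, # degC half-range of the annual cycle
      coldest_doy = 15,         # day of year of the seasonal minimum
      diurnal_amplitude = 3.5,  # degC half-range of the daily cycle
      ar1 = 0.8,                # hour-to-hour weather persistence
      noise_sd = 1.2),          # degC innovation SD of the AR(1) noise
    sampling = list(
      first_date = as.Date("2017-09-20"),
      n_timepoints = 28L,
      interval_days = 7L,
      cultivars = c("cvEarly", "cvLate"),
      bio_reps = 3L,
      tech_reps = 2L),
    phenology = list(
      cp_threshold = c(cvEarly = 72.9, cvLate = 83.9),
      gdh_threshold = 2750,
      forcing_start = as.Date("2017-12-01"),
      forcing_end = as.Date("2018-03-05"),
      forcing_interval_days = 7L,
      forcing_replicates = 3L,
      horizon_weeks = 5L,
      misclassification = 0.02),
    expression = list(
      base_ct = 26,             # target-gene Ct at latent log2 level 0
      ref_base_ct = 21,         # reference-gene Ct
      bio_sd = 0.4,             # cycles, biological replicate noise
      tech_sd = 0.15,           # cycles, technical replicate noise
      good_quality = 0.95,
      bad_quality = 0.5,
      n_bad_samples = 0L,       # planted quality failures (whole samples)
      n_bad_assays = 0L),       # planted quality failures (whole assays)
    gene_panel = default_gene_panel(),
    seed = as.integer(seed)), class = "sim_config")
}

#' Default candidate-gene panel of the generator
#'
#' 36 trajectory genes, six per expression-pattern archetype
#' (`early_eco`, `endo_peak`, `broad`, `eco_peak`, `eco_late`,
#' `budbreak`), four temperature-coupled genes with linear dependence of
#' expression on mean daily temperature (`TC4` with cultivar-specific
#' slope and intercept), three flat reference genes and two silent
#' (never-detected) genes.
#'
#' @param n_per_archetype trajectory genes per archetype (default 6).
#' @param amplitude peak height of trajectory genes in log2 fold-change
#'   units (default 3, i.e. 8-fold).
#' @return data.frame with columns `gene`, `archetype`, `amplitude`,
#'   `intercept`, `slope`, `intercept2`, `slope2` (the `2` columns apply
#'   to the second cultivar; `NA` means same as the first).
#' @export
default_gene_panel <- function(n_per_archetype = 6, amplitude = 3) {
  arch <- c("early_eco", "endo_peak", "broad", "eco_peak", "eco_late",
            "budbreak")
  traj <- data.frame(
    gene = sprintf("G%02d", seq_len(n_per_archetype * length(arch))),
    archetype = rep(arch, each = n_per_archetype),
    amplitude = amplitude,
    intercept = NA_real_, slope = NA_real_,
    intercept2 = NA_real_, slope2 = NA_real_,
    stringsAsFactors = FALSE)
  coupled <- data.frame(
    gene = c("TC1", "TC2", "TC3", "TC4"),
    archetype = "temp_coupled",
    amplitude = NA_real_,
    intercept = c(10, 8, 14, 16),
    slope = c(-0.5, -0.4, -0.6, -0.9),
    intercept2 = c(NA, NA, NA, 12),
    slope2 = c(NA, NA, NA, -0.6),
    stringsAsFactors = FALSE)
  refs <- data.frame(gene = c("REF1", "REF2", "REF3"),
                     archetype = "reference", amplitude = NA_real_,
                     intercept = NA_real_, slope = NA_real_,
                     intercept2 = NA_real_, slope2 = NA_real_)
  silent <- data.frame(gene = c("SIL1", "SIL2"), archetype = "silent",
                       amplitude = NA_real_, intercept = NA_real_,
                       slope = NA_real_, intercept2 = NA_real_,
                       slope2 = NA_real_)
  rbind(traj, coupled, refs, silent)
}

# three independent RNG streams per master seed (temperature, phenology,
# expression), kept below 2^31
sim_streams <- function(seed) derive_subseeds(seed, 3)

#' Simulate an hourly winter temperature series
#'
#' `temp(t) = seasonal sinusoid (day resolution) + diurnal sinusoid +
#' AR(1) noise`. The seasonal component is constant within a calendar day,
#' so with zero noise and zero diurnal amplitude the daily means follow
#' the seasonal sinusoid exactly. The AR(1) noise uses innovation SD
#' `noise_sd` and is started from its stationary distribution.
#'
#' @param config a [default_sim_config()] list.
#' @return An [hourly_temps] series covering the configured season.
#' @export
simulate_temperature <- function(config = default_sim_config()) {
  tp <- config$temperature
  ts <- seq(day_start(config$season_start), day_end(config$season_end),
            by = 3600)
  doy <- as.integer(format(as.Date(ts, tz = "UTC"), "%j"))
  seasonal <- tp$annual_mean -
    tp$seasonal_amplitude * cos(2 * pi * (doy - tp$coldest_doy) / 365.25)
  hour <- as.integer(format(ts, "%H", tz = "UTC"))
  diurnal <- tp$diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
  n <- length(ts)
  noise <- numeric(n)
  if (tp$noise_sd > 0) {
    set.seed(sim_streams(config$seed)[1])
    innov <- stats::rnorm(n, sd = tp$noise_sd)
    noise[1] <- stats::rnorm(1, sd = tp$noise_sd / sqrt(1 - tp$ar1^2))
    for (i in 2:n) noise[i] <- tp$ar1 * noise[i - 1] + innov[i]
  }
  hourly_temps(ts, seasonal + diurnal + noise)
}

#' Simulate dormancy phenology and a forcing-assay table
#'
#' The true transition date of each cultivar is the first day on which
#' cumulative chill portions reach the cultivar's threshold; the true bud
#' break date is the first day after the transition on which the GDH
#' accumulated since the transition reaches the heat threshold. The
#' forcing table scores `forcing_replicates` shoots per weekly cutting
#' date at the forcing horizon: BBCH >= 59 when the cutting date is on or
#' after the transition, < 59 before it, with each replicate misclassified
#' with the configured probability.
#'
#' @param series an [hourly_temps] series spanning the season.
#' @param config a [default_sim_config()] list.
#' @return list with `events` (data.frame `cultivar`, `transition_date`,
#'   `budbreak_date`, `cp_at_transition`) and `forcing` (data.frame in
#'   [transition_from_forcing()] format).
#' @export
simulate_phenology <- function(series, config = default_sim_config()) {
  ph <- config$phenology
  cp <- chill_portions(series)
  gdh <- growing_degree_hours(series)
  days <- seq(as.Date(series$timestamp[1], tz = "UTC"),
              as.Date(series$timestamp[nrow(series)], tz = "UTC"), by = 1)
  ends <- day_end(days)
  idx <- findInterval(as.numeric(ends), as.numeric(cp$timestamp))
  cum_cp <- c(0, cp$cumulative)[idx + 1L]
  cum_gdh <- c(0, gdh$cumulative)[idx + 1L]

  events <- do.call(rbind, lapply(names(ph$cp_threshold), function(cv) {
    thr <- ph$cp_threshold[[cv]]
    hit <- which(cum_cp >= thr)
    if (!length(hit))
      stop("insufficient chill in simulation: threshold ", thr,
           " CP never reached for ", cv, call. = FALSE)
    td <- days[hit[1]]
    gdh_since <- cum_gdh - cum_gdh[hit[1]]
    bb <- which(gdh_since >= ph$gdh_threshold & days > td)
    if (!length(bb))
      stop("insufficient heat in simulation: threshold ", ph$gdh_threshold,
           " GDH never reached for ", cv, call. = FALSE)
    data.frame(cultivar = cv, transition_date = td,
               budbreak_date = days[bb[1]],
               cp_at_transition = cum_cp[hit[1]])
  }))
  rownames(events) <- NULL

  set.seed(sim_streams(config$seed)[2])
  cutting <- seq(as.Date(ph$forcing_start), as.Date(ph$forcing_end),
                 by = ph$forcing_interval_days)
  forcing <- expand.grid(cultivar = events$cultivar, cutting_date = cutting,
                         replicate = seq_len(ph$forcing_replicates),
                         stringsAsFactors = FALSE)
  td <- events$transition_date[match(forcing$cultivar, events$cultivar)]
  released <- forcing$cutting_date >= td
  flip <- stats::runif(nrow(forcing)) < ph$misclassification
  released <- xor(released, flip)
  forcing$weeks_in_forcing <- ph$horizon_weeks
  forcing$bbch_stage <- ifelse(released,
                               sample(59:61, nrow(forcing), replace = TRUE),
                               sample(51:56, nrow(forcing), replace = TRUE))
  forcing <- forcing[order(forcing$cultivar, forcing$cutting_date,
                           forcing$replicate),
                     c("cultivar", "cutting_date", "replicate",
                       "weeks_in_forcing", "bbch_stage")]
  rownames(forcing) <- NULL
  list(events = events, forcing = forcing)
}

# Gaussian bump in days
bump <- function(x, center, width) exp(-(x - center)^2 / (2 * width^2))

# latent log2 fold-change trajectory of one trajectory archetype, as a
# function of days relative to the cultivar's transition (x), days since
# first sampling (s) and days relative to bud break (b)
archetype_latent <- function(archetype, a, x, s, b) {
  switch(archetype,
    early_eco = a * bump(s, 0, 20) + 0.9 * a * bump(x, 40, 20),
    endo_peak = a * bump(x, -55, 18),
    broad = a * bump(x, 0, 50),
    eco_peak = 0.35 * a * bump(x, -45, 12) + a * bump(x, 25, 15),
    eco_late = a * bump(x, 55, 14),
    budbreak = a / (1 + exp(-(b + 2) / 2)),
    stop("unknown archetype id: ", archetype, call. = FALSE))
}

#' Simulate a qPCR Ct table from planted expression trajectories
#'
#' Builds, per gene and cultivar, a latent fold-change trajectory over the
#' sampling dates: trajectory archetypes are Gaussian bumps (a logistic
#' rise for the bud-break archetype) anchored to the cultivar's simulated
#' transition and bud-break dates; temperature-coupled genes follow
#' `fold = intercept + slope x mean daily temperature` (floored at a small
#' positive value); reference genes are flat; silent genes are never
#' detected. Fold changes are converted to target Ct via
#' `Ct = base_ct - log2(fold)`, biological and technical replicate noise
#' is added in Ct (log2) space, and the sample at the first timepoint of
#' the first cultivar serves as the calibrator. Planted quality failures
#' (whole samples / whole assays) receive the `bad_quality` score.
#'
#' @param series an [hourly_temps] series.
#' @param events phenology truth from [simulate_phenology()] (`$events`).
#' @param config a [default_sim_config()] list.
#' @return list with `ct` (Ct table in [read_ct_csv()] format) and `truth`
#'   (list: `panel`, `fold` array gene x timepoint x cultivar of planted
#'   relative fold changes with the calibrator at 1, `sampling_dates`,
#'   `calibrator`, `bad_samples`, `bad_assays`).
#' @export
simulate_expression <- function(series, events,
                                config = default_sim_config()) {
  sp <- config$sampling
  ex <- config$expression
  panel <- config$gene_panel
  dates <- sp$first_date + sp$interval_days * (seq_len(sp$n_timepoints) - 1)
  cvs <- sp$cultivars
  if (!all(cvs %in% events$cultivar))
    stop("phenology events missing cultivar(s): ",
         paste(setdiff(cvs, events$cultivar), collapse = ", "),
         call. = FALSE)
  meant <- vapply(dates, function(d) mean_daily_temperature(series, d),
                  numeric(1))

  # latent log2 levels, genes x dates x cultivars
  latent <- array(NA_real_,
                  dim = c(nrow(panel), length(dates), length(cvs)),
                  dimnames = list(panel$gene, format(dates), cvs))
  for (ci in seq_along(cvs)) {
    ev <- events[events$cultivar == cvs[ci], ]
    x <- as.numeric(dates - ev$transition_date)
    s <- as.numeric(dates - dates[1])
    b <- as.numeric(dates - ev$budbreak_date)
    for (gi in seq_len(nrow(panel))) {
      g <- panel[gi, ]
      latent[gi, , ci] <- switch(g$archetype,
        temp_coupled = {
          int <- if (ci > 1 && !is.na(g$intercept2)) g$intercept2 else g$intercept
          slp <- if (ci > 1 && !is.na(g$slope2)) g$slope2 else g$slope
          log2(pmax(int + slp * meant, 0.05))
        },
        reference = rep(0, length(dates)),
        silent = rep(NA_real_, length(dates)),
        archetype_latent(g$archetype, g$amplitude, x, s, b))
    }
  }

  set.seed(sim_streams(config$seed)[3])
  grid <- expand.grid(tech_rep = seq_len(sp$tech_reps),
                      bio_rep = seq_len(sp$bio_reps),
                      gene = panel$gene,
                      tp = seq_along(dates),
                      cultivar = cvs,
                      stringsAsFactors = FALSE)
  grid$date <- dates[grid$tp]
  grid$sample_id <- paste0(100 + grid$tp, "_", grid$cultivar)
  gi <- match(grid$gene, panel$gene)
  ci <- match(grid$cultivar, cvs)
  lat <- latent[cbind(gi, grid$tp, ci)]
  is_ref <- panel$archetype[gi] == "reference"
  base <- ifelse(is_ref, ex$ref_base_ct, ex$base_ct)
  # biological effects shared by the technical replicates of one unit
  unit <- interaction(grid$sample_id, grid$bio_rep, grid$gene, drop = TRUE)
  bio_eff <- stats::rnorm(nlevels(unit), sd = ex$bio_sd)[as.integer(unit)]
  tech_eff <- stats::rnorm(nrow(grid), sd = ex$tech_sd)
  grid$ct <- base - ifelse(is_ref, 0, lat) + bio_eff + tech_eff
  grid$ct[panel$archetype[gi] == "silent"] <- NA_real_

  grid$quality <- ex$good_quality
  bad_samples <- character(0)
  bad_assays <- character(0)
  if (ex$n_bad_samples > 0) {
    bad_samples <- sample(unique(grid$sample_id), ex$n_bad_samples)
    grid$quality[grid$sample_id %in% bad_samples] <- ex$bad_quality
  }
  if (ex$n_bad_assays > 0) {
    candidates <- panel$gene[!panel$archetype %in% c("reference", "silent")]
    bad_assays <- sample(candidates, ex$n_bad_assays)
    grid$quality[grid$gene %in% bad_assays] <- ex$bad_quality
  }

  ct <- grid[order(grid$cultivar, grid$tp, grid$gene, grid$bio_rep,
                   grid$tech_rep),
             c("sample_id", "date", "cultivar", "gene", "bio_rep",
               "tech_rep", "ct", "quality")]
  rownames(ct) <- NULL

  # planted relative fold changes, calibrator (first timepoint, first
  # cultivar) normalised to 1
  fold <- 2^(sweep(latent, 1, latent[, 1, 1], "-"))
  list(ct = ct,
       truth = list(panel = panel, fold = fold,
                    sampling_dates = dates,
                    calibrator = paste0(101, "_", cvs[1]),
                    bad_samples = bad_samples, bad_assays = bad_assays))
}

#' Simulate a complete coupled dataset
#'
#' Convenience wrapper running [simulate_temperature()],
#' [simulate_phenology()] and [simulate_expression()] with one
#' configuration, returning every dataset the analysis pipeline consumes
#' together with the ground truth it should recover.
#'
#' @param config a [default_sim_config()] list.
#' @return list `series`, `events`, `forcing`, `ct`, `truth`.
#' @export
simulate_dataset <- function(config = default_sim_config()) {
  series <- simulate_temperature(config)
  phen <- simulate_phenology(series, config)
  expr <- simulate_expression(series, phen$events, config)
  list(series = series, events = phen$events, forcing = phen$forcing,
       ct = expr$ct, truth = expr$truth)
}
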