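#' Date the endodormancy-to-ecodormancy transition from a forcing assay
#'
#' In a scion forcing assay, shoots cut weekly are placed under warm
#' long-day conditions and the developmental (BBCH) stage of their terminal
#' bud is scored after a fixed number of weeks. The transition date of a
#' cultivar is the earliest cutting date whose replicate-aggregated stage at
#' the horizon reaches the threshold stage (by default BBCH 59, the balloon
#' stage, after 5 weeks): buds cut on or after that date had fulfilled their
#' chilling requirement.
#'
#' @param observations data.frame with columns `cultivar`, `cutting_date`,
#'   `replicate`, `weeks_in_forcing`, `bbch_stage`.
#' @param stage_threshold BBCH stage that counts as released (default 59).
#' @param horizon_weeks forcing duration scored (default 5 weeks).
#' @param aggregate how replicate stages of one cutting date are combined:
#'   `"median"` (default), `"min"` (all replicates must reach the stage) or
#'   `"any"` (one suffices).
#' @return data.frame with one row per cultivar: `cultivar`,
#'   `transition_date`.
#' @export
transition_from_forcing <- function(observations, stage_threshold = 59,
                                    horizon_weeks = 5,
                                    aggregate = c("median", "min", "any")) {
  aggregate <- match.arg(aggregate)
  req <- c("cultivar", "cutting_date", "replicate", "weeks_in_forcing",
           "bbch_stage")
  if (!all(req %in% names(observations)))
    stop("forcing observations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  obs <- observations[observations$weeks_in_forcing == horizon_weeks, ]
  if (nrow(obs) == 0L)
    stop("no observations at horizon of ", horizon_weeks, " weeks",
         call. = FALSE)
  if (any(obs$bbch_stage < 0 | obs$bbch_stage > 99))
    stop("bbch_stage outside [0, 99]", call. = FALSE)
  obs$cutting_date <- as.Date(obs$cutting_date)
  agg_fun <- switch(aggregate,
                    median = stats::median,
                    min = min,
                    any = max)
  out <- lapply(split(obs, obs$cultivar), function(d) {
    if (length(unique(d$cutting_date)) < 2L)
      stop("need observations from at least two cutting dates for cultivar ",
           d$cultivar[1], call. = FALSE)
    stage <- vapply(split(d$bbch_stage, d$cutting_date), agg_fun, numeric(1))
    dates <- as.Date(names(stage))
    ok <- stage >= stage_threshold
    if (!any(ok))
      stop("endodormancy not released within the observed window for ",
           "cultivar ", d$cultivar[1], call. = FALSE)
    data.frame(cultivar = d$cultivar[1],
               transition_date = min(dates[ok]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chilling requirement of a cultivar
#'
#' Chill accumulated between the start of the chilling season and the
#' endodormancy-to-ecodormancy transition date, under either the
#' chilling-hour (CH) or the dynamic (CP) model. The interval is half-open
#' `(season_start, transition_date]` anchored at the last hour of each day,
#' so the season-start day itself contributes nothing and
#' `transition_date == season_start` yields 0.
#'
#' @param series an [hourly_temps] series.
#' @param season_start calendar day chilling accumulation starts.
#' @param transition_date calendar day of the phase transition.
#' @param model `"CH"` or `"CP"`.
#' @param ... passed to [chilling_hours()] or [chill_portions()] (band
#'   boundaries, kinetic constants).
#' @return Accumulated chill units (hours or portions).
#' @export
chilling_requirement <- function(series, season_start, transition_date,
                                 model = c("CP", "CH"), ...) {
  model <- match.arg(model)
  season_start <- as.Date(season_start)
  transition_date <- as.Date(transition_date)
  if (transition_date < season_start)
    stop("transition_date precedes season_start", call. = FALSE)
  acc <- switch(model,
                CH = chilling_hours(series, ...),
                CP = chill_portions(series, ...))
  accumulate_between(acc, season_start, transition_date)
}

#' Heat requirement for bud break
#'
#' Growing degree hours accumulated in `(transition_date, budbreak_date]`.
#'
#' @param series an [hourly_temps] series.
#' @param transition_date calendar day of the endo-to-ecodormancy
#'   transition.
#' @param budbreak_date calendar day of bud break.
#' @param params a [gdh_params()] list.
#' @return Accumulated GDH.
#' @export
heat_requirement <- function(series, transition_date, budbreak_date,
                             params = gdh_params()) {
  transition_date <- as.Date(transition_date)
  budbreak_date <- as.Date(budbreak_date)
  if (budbreak_date < transition_date)
    stop("budbreak_date precedes transition_date", call. = FALSE)
  acc <- growing_degree_hours(series, params)
  accumulate_between(acc, transition_date, budbreak_date)
}

#' Per-cultivar dormancy phenology report
#'
#' Combines a forcing-assay transition estimate with field bud-break dates
#' and a temperature record into one report of transition date, bud-break
#' window, chilling requirement in both CH and CP units, and the heat
#' requirement range over the bud-break window.
#'
#' @param series an [hourly_temps] series.
#' @param forcing forcing observations (see [transition_from_forcing()]).
#' @param budbreak data.frame with columns `cultivar`, `budbreak_start`,
#'   `budbreak_end` (calendar days of the field bud-break window).
#' @param season_start day chilling accumulation starts; default the first
#'   cutting date minus nothing, i.e. the earliest date in `forcing` is NOT
#'   used - the caller should pass the first sampling date of the campaign
#'   or a fixed convention such as Sept 1. When `NULL`, the first day of the
#'   temperature series is used and flagged in the output.
#' @param stage_threshold,horizon_weeks,aggregate passed to
#'   [transition_from_forcing()].
#' @param gdh passed to [heat_requirement()] as `params`.
#' @return data.frame with one row per cultivar: `cultivar`,
#'   `transition_date`, `budbreak_start`, `budbreak_end`,
#'   `chilling_requirement_ch`, `chilling_requirement_cp`,
#'   `heat_requirement_gdh_min`, `heat_requirement_gdh_max`,
#'   `season_start`.
#' @export
phenology_events <- function(series, forcing, budbreak, season_start = NULL,
                             stage_threshold = 59, horizon_weeks = 5,
                             aggregate = "median", gdh = gdh_params()) {
  stopifnot(inherits(series, "hourly_temps"))
  if (is.null(season_start)) {
    season_start <- as.Date(series$timestamp[1], tz = "UTC")
  } else season_start <- as.Date(season_start)
  trans <- transition_from_forcing(forcing, stage_threshold = stage_threshold,
                                   horizon_weeks = horizon_weeks,
                                   aggregate = aggregate)
  bb <- budbreak
  bb$cultivar <- as.character(bb$cultivar)
  rows <- lapply(seq_len(nrow(trans)), function(i) {
    cv <- as.character(trans$cultivar[i])
    td <- trans$transition_date[i]
    b <- bb[bb$cultivar == cv, , drop = FALSE]
    if (nrow(b) != 1L)
      stop("need exactly one bud-break window for cultivar ", cv,
           call. = FALSE)
    bs <- as.Date(b$budbreak_start); be <- as.Date(b$budbreak_end)
    if (!(td < bs && bs <= be))
      stop("require transition < budbreak_start <= budbreak_end for ", cv,
           call. = FALSE)
    data.frame(
      cultivar = cv,
      transition_date = td,
      budbreak_start = bs,
      budbreak_end = be,
      chilling_requirement_ch =
        chilling_requirement(series, season_start, td, model = "CH"),
      chilling_requirement_cp =
        chilling_requirement(series, season_start, td, model = "CP"),
      heat_requirement_gdh_min =
        heat_requirement(series, td, bs, params = gdh),
      heat_requirement_gdh_max =
        heat_requirement(series, td, be, params = gdh),
      season_start = season_start)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
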