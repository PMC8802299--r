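#' Kinetic constants of the two-step dynamic chill model
#'
#' The dynamic model tracks a thermally labile intermediate that relaxes
#' toward a temperature-dependent equilibrium at a temperature-dependent
#' rate; whenever the intermediate completes (reaches 1), a
#' temperature-dependent fraction is banked irreversibly as one chill
#' portion and the remainder carries over. The default constants are the
#' canonical published parameter set used by standard implementations;
#' temperatures enter the kinetics in Kelvin.
#'
#' @param slp slope of the transfer-function argument (dimensionless).
#' @param tetmlt transition temperature of the partition function (K).
#' @param a0,a1 pre-exponential rate factors of formation and destruction.
#' @param e0,e1 activation energies of formation and destruction (K).
#' @return A named list of class `dynamic_model_params`.
#' @export
dynamic_model_params <- function(slp = 1.6, tetmlt = 277, a0 = 139500,
                                 a1 = 2.567e18, e0 = 4153.5, e1 = 12888.8) {
  p <- list(slp = slp, tetmlt = tetmlt, a0 = a0, a1 = a1, e0 = e0, e1 = e1)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1))))
    stop("all dynamic-model constants must be single positive numbers",
         call. = FALSE)
  structure(p, class = "dynamic_model_params")
}

#' Cardinal temperatures of the ASYMCUR growing-degree-hour model
#'
#' @param t_base base temperature in degC below which no heat accrues
#'   (default 4).
#' @param t_optimal optimal temperature in degC at which the full hourly
#'   credit `t_optimal - t_base` accrues (default 25).
#' @param t_critical critical temperature in degC above which no heat
#'   accrues (default 36).
#' @param stress_factor multiplier in (0, 1] applied to every hourly credit
#'   (default 1).
#' @return A named list of class `gdh_params`.
#' @export
gdh_params <- function(t_base = 4, t_optimal = 25, t_critical = 36,
                       stress_factor = 1) {
  if (!(t_base < t_optimal && t_optimal < t_critical))
    stop("require t_base < t_optimal < t_critical", call. = FALSE)
  if (!(stress_factor > 0 && stress_factor <= 1))
    stop("stress_factor must lie in (0, 1]", call. = FALSE)
  structure(list(t_base = t_base, t_optimal = t_optimal,
                 t_critical = t_critical, stress_factor = stress_factor),
            class = "gdh_params")
}

new_thermal_acc <- function(series, model, incremental, params) {
  structure(
    data.frame(timestamp = series$timestamp,
               incremental = incremental,
               cumulative = cumsum(incremental)),
    model = model, params = params,
    class = c("thermal_acc", "data.frame"))
}

#' @export
print.thermal_acc <- function(x, ...) {
  cat(sprintf("<thermal_acc model=%s> %d hours, total %.3f units\n",
              attr(x, "model"), nrow(x), x$cumulative[nrow(x)]))
  invisible(x)
}

#' Chilling hours (Weinberger band model)
#'
#' Credits one chill hour for every hour whose temperature lies in the
#' effective chilling band, by default `low < T <= high` with the classic
#' 0-7.2 degC band.
#'
#' @param series an [hourly_temps] series.
#' @param low,high band boundaries in degC (defaults 0 and 7.2); the band is
#'   open at `low` and closed at `high`.
#' @return A `thermal_acc` data.frame with columns `timestamp`,
#'   `incremental` (0/1) and `cumulative`.
#' @export
chilling_hours <- function(series, low = 0, high = 7.2) {
  stopifnot(inherits(series, "hourly_temps"))
  if (!(low < high)) stop("require low < high", call. = FALSE)
  inc <- as.numeric(series$temp_c > low & series$temp_c <= high)
  new_thermal_acc(series, "CH", inc, list(low = low, high = high))
}

#' Chill portions (dynamic model)
#'
#' Hour-by-hour two-step kinetic model of chill accumulation: a labile
#' intermediate relaxes toward its temperature-dependent equilibrium
#' `xs = (a0/a1) exp((e1 - e0)/T)` at rate `k1 = a1 exp(-e1/T)` (T in
#' Kelvin). At the start of any hour in which the intermediate has reached
#' 1, the fraction `xi(T)` of it is banked irreversibly as chill portions
#' and `(1 - xi)` of the intermediate carries forward. The intermediate
#' starts at 0 at the beginning of the series.
#'
#' @param series an [hourly_temps] series.
#' @param params a [dynamic_model_params()] list.
#' @return A `thermal_acc` data.frame; `incremental` holds the portions
#'   banked each hour, `cumulative` the running chill-portion total.
#' @export
chill_portions <- function(series, params = dynamic_model_params()) {
  stopifnot(inherits(series, "hourly_temps"),
            inherits(params, "dynamic_model_params"))
  tk <- series$temp_c + 273
  ftmprt <- params$slp * params$tetmlt * (tk - params$tetmlt) / tk
  sr <- exp(ftmprt)
  xi <- sr / (1 + sr)                                  # banked fraction
  xs <- params$a0 / params$a1 * exp(-(params$e0 - params$e1) / tk)
  ak1 <- params$a1 * exp(-params$e1 / tk)              # relaxation rate
  decay <- exp(-ak1)
  n <- length(tk)
  inc <- numeric(n)
  inter <- 0
  for (i in seq_len(n)) {
    if (inter >= 1) {                                  # bank, carry remainder
      inter <- inter * (1 - xi_prev)
    }
    inter <- xs[i] - (xs[i] - inter) * decay[i]
    if (inter >= 1) inc[i] <- inter * xi[i]
    xi_prev <- xi[i]
  }
  new_thermal_acc(series, "CP", inc, params)
}

#' Growing degree hours (ASYMCUR model)
#'
#' Asymmetric curvilinear hourly heat response between base, optimal and
#' critical temperatures: zero credit at or below `t_base` and at or above
#' `t_critical`; a half-cosine rise from 0 at `t_base` to
#' `t_optimal - t_base` at `t_optimal`; a quarter-cosine fall from that
#' maximum back to 0 at `t_critical`. Each hourly credit is multiplied by
#' `stress_factor`.
#'
#' @param series an [hourly_temps] series.
#' @param params a [gdh_params()] list.
#' @return A `thermal_acc` data.frame of hourly and cumulative GDH.
#' @export
growing_degree_hours <- function(series, params = gdh_params()) {
  stopifnot(inherits(series, "hourly_temps"), inherits(params, "gdh_params"))
  inc <- gdh_hourly(series$temp_c, params)
  new_thermal_acc(series, "GDH", inc, params)
}

# vectorised hourly GDH response
gdh_hourly <- function(temp_c, params) {
  tb <- params$t_base; tu <- params$t_optimal; tc <- params$t_critical
  f <- params$stress_factor
  amp <- tu - tb
  inc <- numeric(length(temp_c))
  rise <- temp_c > tb & temp_c <= tu
  fall <- temp_c > tu & temp_c < tc
  inc[rise] <- f * amp / 2 * (1 + cos(pi + pi * (temp_c[rise] - tb) / amp))
  inc[fall] <- f * amp * (1 + cos(pi / 2 + pi / 2 * (temp_c[fall] - tu) /
                                    (tc - tu)))
  inc
}

#' Units accumulated in a half-open interval
#'
#' Sums the hourly increments of a thermal accumulation over the half-open
#' interval `(start, end]`. Endpoints may be instants (POSIXct) or calendar
#' days, which anchor to their last hour (23:00), so two equal days bound an
#' empty interval. The sum is additive over adjacent intervals.
#'
#' @param acc a `thermal_acc` from [chilling_hours()], [chill_portions()] or
#'   [growing_degree_hours()].
#' @param start,end interval endpoints, `start <= end`, both within the
#'   series span (the instant one hour before the first timestamp counts as
#'   within, so the full span can be queried).
#' @return Accumulated units as a single number.
#' @export
accumulate_between <- function(acc, start, end) {
  stopifnot(inherits(acc, "thermal_acc"))
  start <- as_instant(start)
  end <- as_instant(end)
  if (start > end) stop("start must not be after end", call. = FALSE)
  first <- acc$timestamp[1]
  last <- acc$timestamp[nrow(acc)]
  if (start < first - 3600 || end > last)
    stop("interval outside the accumulation span", call. = FALSE)
  sum(acc$incremental[acc$timestamp > start & acc$timestamp <= end])
}

as_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(day_end(x))
  # strings: date-only strings anchor to day end, otherwise parse as instant
  if (is.character(x) && !grepl(":", x)) return(day_end(as.Date(x)))
  as.POSIXct(x, tz = "UTC")
}

#' Chill accumulated in the window before a sampling day
#'
#' Accumulation over the half-open window ending at the last hour of `date`
#' and starting `window_days` earlier, e.g. the sum of chill hours or chill
#' portions of the two weeks preceding (and including) a sampling date.
#'
#' @param acc a `thermal_acc`.
#' @param date calendar day ending the window.
#' @param window_days window length in days (default 14).
#' @param partial what to do when the window starts before the series:
#'   `"error"` (default) or `"truncate"`, which sums the covered part and
#'   marks the result with attribute `truncated = TRUE`.
#' @return Accumulated units; attribute `truncated` signals a shortened
#'   window when `partial = "truncate"`.
#' @export
windowed_chill_sum <- function(acc, date, window_days = 14,
                               partial = c("error", "truncate")) {
  stopifnot(inherits(acc, "thermal_acc"), window_days >= 1)
  partial <- match.arg(partial)
  end <- day_end(date)
  start <- end - window_days * 86400
  first <- acc$timestamp[1]
  last <- acc$timestamp[nrow(acc)]
  if (end <= first - 3600 || start >= last)
    stop("window (", format(start), ", ", format(end),
         "] lies outside the accumulation span", call. = FALSE)
  truncated <- FALSE
  if (start < first - 3600) {
    if (partial == "error")
      stop("window starts before the series; use partial = \"truncate\"",
           call. = FALSE)
    start <- first - 3600
    truncated <- TRUE
  }
  if (end > last) {
    if (partial == "error")
      stop("window ends after the series; use partial = \"truncate\"",
           call. = FALSE)
    end <- last
    truncated <- TRUE
  }
  out <- accumulate_between(acc, start, end)
  attr(out, "truncated") <- truncated
  out
}

#' Write a thermal accumulation as CSV
#'
#' Columns `timestamp,model,incremental,cumulative`.
#'
#' @param acc a `thermal_acc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accumulation_csv <- function(acc, path) {
  stopifnot(inherits(acc, "thermal_acc"))
  out <- data.frame(
    timestamp = format(acc$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    model = attr(acc, "model"),
    incremental = acc$incremental,
    cumulative = acc$cumulative)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
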