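#' Temperature covariates at sampling dates
#'
#' For each sampling date, computes the mean daily temperature at that date
#' and the chill accumulated within `window_days` before sampling under the
#' chilling-hour and dynamic models (optionally also GDH). Windows that
#' start before the temperature record are truncated and flagged.
#'
#' @param series an [hourly_temps] series.
#' @param sampling_dates vector of calendar days.
#' @param window_days length of the pre-sampling window (default 14).
#' @param include_gdh also compute a `gdh_sum` column (default FALSE).
#' @param ch_low,ch_high chilling-hour band (defaults 0, 7.2).
#' @return data.frame with columns `date`, `mean_daily_temp`, `ch_sum`,
#'   `cp_sum` (and `gdh_sum`), and `truncated` flagging shortened windows.
#' @export
build_covariates <- function(series, sampling_dates, window_days = 14,
                             include_gdh = FALSE, ch_low = 0, ch_high = 7.2) {
  stopifnot(inherits(series, "hourly_temps"))
  dates <- sort(unique(as.Date(sampling_dates)))
  ch <- chilling_hours(series, low = ch_low, high = ch_high)
  cp <- chill_portions(series)
  gdh <- if (include_gdh) growing_degree_hours(series)
  rows <- lapply(dates, function(d) {
    chs <- windowed_chill_sum(ch, d, window_days, partial = "truncate")
    cps <- windowed_chill_sum(cp, d, window_days, partial = "truncate")
    r <- data.frame(date = d,
                    mean_daily_temp = mean_daily_temperature(series, d),
                    ch_sum = as.numeric(chs),
                    cp_sum = as.numeric(cps))
    if (include_gdh)
      r$gdh_sum <- as.numeric(windowed_chill_sum(gdh, d, window_days,
                                                 partial = "truncate"))
    r$truncated <- isTRUE(attr(chs, "truncated"))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

covariate_cols <- function(covariates) {
  setdiff(names(covariates), c("date", "truncated"))
}

# one Pearson correlation + OLS fit; returns a one-row data.frame
cor_fit_row <- function(gene, covariate, group, x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  base <- data.frame(gene = gene, covariate = covariate, group = group,
                     n = n, r = NA_real_, p = NA_real_, slope = NA_real_,
                     intercept = NA_real_, reason = NA_character_,
                     stringsAsFactors = FALSE)
  if (n < 3) { base$reason <- "fewer than 3 pairs"; return(base) }
  if (stats::sd(y) == 0) { base$reason <- "zero variance (expression)"; return(base) }
  if (stats::sd(x) == 0) { base$reason <- "zero variance (covariate)"; return(base) }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  base$r <- unname(ct$estimate)
  base$p <- ct$p.value
  base$slope <- unname(stats::coef(fit)[2])
  base$intercept <- unname(stats::coef(fit)[1])
  base
}

#' Correlate expression profiles with temperature covariates
#'
#' Pearson correlation (with two-sided p-value from the t transform) of
#' per-timepoint mean expression against each temperature covariate, for
#' every gene, pooled over cultivars and/or per cultivar. Missing
#' expression cells are dropped pairwise; zero-variance cases are reported
#' as missing with a reason. An optional Benjamini-Hochberg adjusted-p
#' column can be added as an extension beyond the per-test p-values.
#'
#' @param profiles an `expression_profiles` data.frame.
#' @param covariates covariate table from [build_covariates()].
#' @param grouping `"pooled"`, `"by_cultivar"` or `"both"` (default).
#' @param include_truncated keep sampling dates whose covariate window was
#'   truncated at the series start (default FALSE).
#' @param bh_adjust append a `p_bh` column of Benjamini-Hochberg adjusted
#'   p-values across all reported tests (default FALSE).
#' @return data.frame with columns `gene`, `covariate`, `group`, `n`, `r`,
#'   `p`, `slope`, `intercept`, `reason`.
#' @export
correlate <- function(profiles, covariates,
                      grouping = c("both", "pooled", "by_cultivar"),
                      include_truncated = FALSE, bh_adjust = FALSE) {
  grouping <- match.arg(grouping)
  if (!include_truncated && "truncated" %in% names(covariates))
    covariates <- covariates[!covariates$truncated, , drop = FALSE]
  if (nrow(covariates) == 0L)
    stop("no usable covariate rows (all truncated?)", call. = FALSE)
  d <- merge(as.data.frame(profiles), covariates, by = "date")
  covs <- covariate_cols(covariates)
  groups <- list()
  if (grouping %in% c("both", "pooled")) groups[["pooled"]] <- d
  if (grouping %in% c("both", "by_cultivar"))
    groups <- c(groups, split(d, d$cultivar))
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (gene in unique(g$gene)) {
      gg <- g[g$gene == gene, ]
      for (cov in covs) {
        rows[[length(rows) + 1L]] <-
          cor_fit_row(gene, cov, gname, gg[[cov]], gg$mean_rel_expr)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (bh_adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-group linear fit of one gene's expression on one covariate
#'
#' Ordinary least squares of mean expression on a temperature covariate
#' within each requested group (cultivar), with the between-group slope
#' difference when exactly two groups are compared — the readout used to
#' ask whether two cultivars differ in the temperature sensitivity of a
#' gene's expression.
#'
#' @param profiles an `expression_profiles` data.frame.
#' @param covariates covariate table from [build_covariates()].
#' @param gene gene name.
#' @param covariate covariate column name (e.g. `"mean_daily_temp"`).
#' @param groups cultivar names to fit (default: all in `profiles`).
#' @param include_truncated see [correlate()].
#' @return list with `fits` (data.frame `group`, `n`, `slope`, `intercept`,
#'   `r`, `p`) and, when exactly two groups are fit, `slope_difference`
#'   (first minus second).
#' @export
fit_line_by_group <- function(profiles, covariates, gene, covariate,
                              groups = NULL, include_truncated = FALSE) {
  if (!include_truncated && "truncated" %in% names(covariates))
    covariates <- covariates[!covariates$truncated, , drop = FALSE]
  d <- merge(as.data.frame(profiles), covariates, by = "date")
  d <- d[d$gene == gene, , drop = FALSE]
  if (nrow(d) == 0L) stop("gene '", gene, "' absent", call. = FALSE)
  if (!covariate %in% names(d))
    stop("covariate '", covariate, "' absent", call. = FALSE)
  if (is.null(groups)) groups <- sort(unique(d$cultivar))
  missing_grp <- setdiff(groups, d$cultivar)
  if (length(missing_grp))
    stop("group(s) absent: ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  fits <- do.call(rbind, lapply(groups, function(grp) {
    gg <- d[d$cultivar == grp, ]
    row <- cor_fit_row(gene, covariate, grp, gg[[covariate]],
                       gg$mean_rel_expr)
    data.frame(group = grp, n = row$n, slope = row$slope,
               intercept = row$intercept, r = row$r, p = row$p)
  }))
  rownames(fits) <- NULL
  out <- list(fits = fits)
  if (nrow(fits) == 2L)
    out$slope_difference <- fits$slope[1] - fits$slope[2]
  out
}

#' Gene x covariate correlation matrices per group
#'
#' Rearranges a long correlation report into rectangular matrices of `r`
#' with aligned `p` and `n` matrices, one set per group. Missing
#' correlations stay `NA`, never 0.
#'
#' @param reports long report from [correlate()].
#' @return named list (per group) of lists with matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(reports) {
  if (nrow(reports) == 0L) stop("empty correlation report", call. = FALSE)
  lapply(split(reports, reports$group), function(g) {
    genes <- sort(unique(g$gene))
    covs <- unique(g$covariate)
    mk <- function(col, mode = NA_real_) {
      m <- matrix(mode, length(genes), length(covs),
                  dimnames = list(genes, covs))
      m[cbind(match(g$gene, genes), match(g$covariate, covs))] <- g[[col]]
      m
    }
    list(r = mk("r"), p = mk("p"), n = mk("n"))
  })
}

#' Highest temperature at which a gene is still expressed
#'
#' Among the sampling dates at which a gene's mean expression exceeds the
#' detection floor, returns the maximum mean daily temperature — an
#' estimate of the temperature ceiling below which the gene is expressed
#' in the field. A gene expressed at every timepoint returns the overall
#' maximum, flagged `"no contrast"`; a gene never expressed returns `NA`
#' with the reason.
#'
#' @param profiles an `expression_profiles` data.frame (one or more genes).
#' @param covariates covariate table from [build_covariates()] (needs
#'   `mean_daily_temp`).
#' @param gene gene name.
#' @param cultivar optional cultivar to restrict to.
#' @param detection_floor expression strictly above this counts as
#'   expressed (default 0).
#' @return Numeric temperature in degC with attribute `note`, or `NA` with
#'   attribute `reason = "never expressed"`.
#' @export
expression_onset_temperature <- function(profiles, covariates, gene,
                                         cultivar = NULL,
                                         detection_floor = 0) {
  d <- merge(as.data.frame(profiles), covariates, by = "date")
  d <- d[d$gene == gene, , drop = FALSE]
  if (!is.null(cultivar)) d <- d[d$cultivar == cultivar, , drop = FALSE]
  if (nrow(d) == 0L) stop("gene '", gene, "' absent", call. = FALSE)
  expressed <- !is.na(d$mean_rel_expr) & d$mean_rel_expr > detection_floor
  if (!any(expressed)) {
    out <- NA_real_
    attr(out, "reason") <- "never expressed"
    return(out)
  }
  out <- max(d$mean_daily_temp[expressed])
  if (all(expressed)) attr(out, "note") <- "no contrast"
  out
}
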