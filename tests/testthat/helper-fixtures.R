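# shared fixture builders and independent oracles

# constant- or vector-valued hourly series starting at a fixed instant
make_series <- function(temp_c, start = "2017-11-01 00:00:00") {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = 3600,
            length.out = length(temp_c))
  hourly_temps(ts, temp_c)
}

# independent oracle: literal hour-by-hour transcription of the dynamic
# model's update equations, scalar loop, kept deliberately naive and
# separate from the package implementation
oracle_chill_portions <- function(temp_c) {
  slp <- 1.6; tetmlt <- 277; a0 <- 139500; a1 <- 2.567e18
  e0 <- 4153.5; e1 <- 12888.8
  delt <- numeric(length(temp_c)); prev_e <- 0; prev_xi <- 0
  for (i in seq_along(temp_c)) {
    tk <- temp_c[i] + 273
    sr <- exp(slp * tetmlt * (tk - tetmlt) / tk)
    xi <- sr / (1 + sr)
    xs <- a0 / a1 * exp(-(e0 - e1) / tk)
    ak1 <- a1 * exp(-e1 / tk)
    inter_s <- if (i == 1) 0 else
      if (prev_e < 1) prev_e else prev_e * (1 - prev_xi)
    inter_e <- xs - (xs - inter_s) * exp(-ak1)
    delt[i] <- if (inter_e >= 1) inter_e * xi else 0
    prev_e <- inter_e; prev_xi <- xi
  }
  cumsum(delt)
}

# small Ct table builder: one row per reaction
make_ct <- function(sample_id, date, cultivar, gene, bio_rep, tech_rep,
                    ct, quality = 0.95) {
  data.frame(sample_id = sample_id, date = as.Date(date),
             cultivar = cultivar, gene = gene, bio_rep = bio_rep,
             tech_rep = tech_rep, ct = ct, quality = quality,
             stringsAsFactors = FALSE)
}

# noiseless two-gene Ct fixture with known fold changes relative to the
# calibrator sample "S1": gene "T" has fold f per sample, reference "R"
# is flat at ref_ct
make_fold_ct <- function(folds, ref_ct = 20, base_ct = 25) {
  rows <- list()
  for (i in seq_along(folds)) {
    sid <- paste0("S", i)
    d <- as.Date("2017-10-01") + 7 * (i - 1)
    for (b in 1:2) for (tr in 1:2) {
      rows[[length(rows) + 1L]] <- make_ct(sid, d, "cvA", "T", b, tr,
                                           base_ct - log2(folds[i]))
      rows[[length(rows) + 1L]] <- make_ct(sid, d, "cvA", "R", b, tr, ref_ct)
    }
  }
  do.call(rbind, rows)
}

traj_archetypes <- c("early_eco", "endo_peak", "broad", "eco_peak",
                     "eco_late", "budbreak")
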