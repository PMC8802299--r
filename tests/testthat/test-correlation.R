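one_gene_profiles <- function(expr, dates, cultivar = "cvA", gene = "T") {
  out <- data.frame(gene = gene, date = dates, cultivar = cultivar,
                    mean_rel_expr = expr, n_bio = 3L)
  class(out) <- c("expression_profiles", "data.frame")
  out
}

test_that("covariates combine daily means with 14-day chill windows", {
  s <- make_series(rep(5, 24 * 60), start = "2017-11-01 00:00:00")
  dates <- as.Date("2017-11-20") + 7 * 0:3
  cov <- build_covariates(s, dates)
  expect_equal(cov$ch_sum, rep(336, 4))
  expect_equal(cov$mean_daily_temp, rep(5, 4))
  expect_false(any(cov$truncated))
  warm <- make_series(rep(20, 24 * 60), start = "2017-11-01 00:00:00")
  expect_equal(build_covariates(warm, dates)$ch_sum, rep(0, 4))
  # early date with only partial history is flagged truncated
  cov2 <- build_covariates(s, as.Date("2017-11-05"))
  expect_true(cov2$truncated)
  expect_error(build_covariates(s, as.Date("2019-01-01")), "outside")
})

test_that("perfect linear coupling gives r = -1 and zero variance is reported", {
  set.seed(1)
  s <- simulate_temperature(default_sim_config(1))
  dates <- as.Date("2017-10-15") + 7 * 0:19
  cov <- build_covariates(s, dates)
  expr <- 10 - 0.5 * cov$mean_daily_temp
  rep1 <- correlate(one_gene_profiles(expr, dates), cov, grouping = "pooled")
  row <- rep1[rep1$covariate == "mean_daily_temp", ]
  expect_equal(row$r, -1, tolerance = 1e-9)
  expect_equal(row$slope, -0.5, tolerance = 1e-9)
  expect_lt(row$p, 1e-10)
  # slope sign equals sign of r wherever both are defined
  ok <- !is.na(rep1$r)
  expect_true(all(sign(rep1$slope[ok]) == sign(rep1$r[ok])))
  # constant expression -> missing with reason
  repc <- correlate(one_gene_profiles(rep(2, 20), dates), cov,
                    grouping = "pooled")
  expect_true(all(is.na(repc$r)))
  expect_match(repc$reason[1], "zero variance")
})

test_that("r is invariant to positive affine rescaling", {
  set.seed(8)
  s <- simulate_temperature(default_sim_config(8))
  dates <- as.Date("2017-10-15") + 7 * 0:19
  cov <- build_covariates(s, dates)
  expr <- 5 - 0.3 * cov$mean_daily_temp + rnorm(20, 0, 0.5)
  r1 <- correlate(one_gene_profiles(expr, dates), cov, grouping = "pooled")
  r2 <- correlate(one_gene_profiles(3 + 10 * expr, dates), cov,
                  grouping = "pooled")
  expect_equal(r1$r, r2$r, tolerance = 1e-9)
})

test_that("group fits recover planted slopes and their difference", {
  set.seed(30)
  s <- simulate_temperature(default_sim_config(30))
  dates <- as.Date("2017-10-01") + 7 * 0:27
  cov <- build_covariates(s, dates, window_days = 14)
  tt <- cov$mean_daily_temp
  noise_sd <- 0.02 * abs(-0.8) * diff(range(tt))
  pa <- one_gene_profiles(12 - 0.8 * tt + rnorm(28, 0, noise_sd), dates, "cvA")
  pb <- one_gene_profiles(6 - 0.3 * tt + rnorm(28, 0, noise_sd), dates, "cvB")
  prof <- rbind(pa, pb)
  class(prof) <- c("expression_profiles", "data.frame")
  fit <- fit_line_by_group(prof, cov, "T", "mean_daily_temp")
  sa <- fit$fits$slope[fit$fits$group == "cvA"]
  sb <- fit$fits$slope[fit$fits$group == "cvB"]
  expect_lt(abs(sa - -0.8) / 0.8, 0.1)
  expect_lt(abs(sb - -0.3) / 0.3, 0.1)
  expect_equal(fit$slope_difference, sa - sb)
  # identical data in both groups -> zero slope difference
  pb2 <- pa; pb2$cultivar <- "cvB"
  prof2 <- rbind(pa, pb2)
  fit2 <- fit_line_by_group(prof2, cov, "T", "mean_daily_temp")
  expect_equal(fit2$slope_difference, 0, tolerance = 1e-12)
  # single group requested -> no difference field
  fit1 <- fit_line_by_group(prof, cov, "T", "mean_daily_temp", groups = "cvA")
  expect_null(fit1$slope_difference)
  expect_error(fit_line_by_group(prof, cov, "T", "mean_daily_temp",
                                 groups = "cvZ"), "absent")
})

test_that("correlation matrices mirror the long report including missing cells", {
  set.seed(2)
  s <- simulate_temperature(default_sim_config(2))
  dates <- as.Date("2017-10-15") + 7 * 0:14
  cov <- build_covariates(s, dates)
  p1 <- one_gene_profiles(10 - 0.4 * cov$mean_daily_temp, dates, gene = "A")
  p2 <- one_gene_profiles(rep(1, 15), dates, gene = "B")  # zero variance
  prof <- rbind(p1, p2)
  class(prof) <- c("expression_profiles", "data.frame")
  rep_long <- correlate(prof, cov, grouping = "pooled")
  mats <- correlation_matrix(rep_long)
  expect_equal(dim(mats$pooled$r), c(2, 3))
  for (i in seq_len(nrow(rep_long))) {
    got <- mats$pooled$r[rep_long$gene[i], rep_long$covariate[i]]
    if (is.na(rep_long$r[i])) expect_true(is.na(got))
    else expect_equal(got, rep_long$r[i])
  }
})

test_that("expression onset temperature is the warmest expressed timepoint", {
  dates <- as.Date("2017-10-15") + 7 * 0:4
  cov <- data.frame(date = dates, mean_daily_temp = c(12, 9, 5, 2, 7),
                    ch_sum = 0, cp_sum = 0, truncated = FALSE)
  prof <- one_gene_profiles(c(0, 0.5, 2, 3, 1), dates)
  expect_equal(expression_onset_temperature(prof, cov, "T"), 9,
               ignore_attr = TRUE)
  # expressed everywhere: overall max, flagged
  prof2 <- one_gene_profiles(rep(1, 5), dates)
  v <- expression_onset_temperature(prof2, cov, "T")
  expect_equal(as.numeric(v), 12)
  expect_equal(attr(v, "note"), "no contrast")
  # never expressed
  prof3 <- one_gene_profiles(rep(0, 5), dates)
  v3 <- expression_onset_temperature(prof3, cov, "T")
  expect_true(is.na(v3))
  expect_equal(attr(v3, "reason"), "never expressed")
  # step-function gene switching off above a planted threshold
  set.seed(3)
  s <- simulate_temperature(default_sim_config(3))
  dd <- as.Date("2017-10-15") + 7 * 0:24
  cc <- build_covariates(s, dd)
  expr <- ifelse(cc$mean_daily_temp < 9, 2, 0)
  v4 <- expression_onset_temperature(one_gene_profiles(expr, dd), cc, "T")
  expect_lte(as.numeric(v4), 9)
})
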