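test_that("qc filtering removes failing samples and assays and logs them", {
  base <- make_fold_ct(c(1, 2, 4))
  out <- qc_filter(base, 0.65)
  expect_identical(out$kept, base)           # all qualities 0.95: identity
  expect_equal(nrow(out$exclusions), 0)

  bad <- base
  bad$quality[bad$sample_id == "S2"] <- 0.5
  out2 <- qc_filter(bad, 0.65)
  expect_false(any(out2$kept$sample_id == "S2"))
  expect_equal(out2$exclusions$unit, "S2")
  expect_equal(out2$exclusions$unit_type, "sample")

  # planted 2 bad assays + 1 bad sample -> exactly those 3 units logged
  cfg <- default_sim_config(9)
  cfg$expression$n_bad_samples <- 1L
  cfg$expression$n_bad_assays <- 2L
  sim <- simulate_dataset(cfg)
  out3 <- qc_filter(sim$ct, 0.65)
  expect_setequal(out3$exclusions$unit,
                  c(sim$truth$bad_samples, sim$truth$bad_assays))
  expect_equal(nrow(out3$exclusions), 3)

  allbad <- base
  allbad$quality <- 0.1
  expect_error(qc_filter(allbad, 0.65), "unusable")
})

test_that("reference stability ranks a noisy candidate last", {
  set.seed(21)
  n <- 30
  rows <- list()
  for (i in seq_len(n)) {
    sid <- paste0("S", i)
    d <- as.Date("2017-10-01") + i
    base <- rnorm(1, 20, 0.3)            # shared sample-loading shift
    rows[[length(rows) + 1L]] <- make_ct(sid, d, "cvA", "RA", 1, 1, base)
    rows[[length(rows) + 1L]] <- make_ct(sid, d, "cvA", "RB", 1, 1,
                                         base + 1.5 + rnorm(1, 0, 0.05))
    rows[[length(rows) + 1L]] <- make_ct(sid, d, "cvA", "RC", 1, 1,
                                         base + rnorm(1, 0, 1.5))
  }
  tab <- reference_stability(do.call(rbind, rows), c("RA", "RB", "RC"))
  expect_equal(tab$gene[which.max(tab$comprehensive_rank)], "RC")
  expect_true(all(diff(tab$comprehensive_rank) >= 0))  # sorted, lower = stabler

  # two candidates offset by an exact constant have zero variation
  const <- do.call(rbind, lapply(1:10, function(i)
    rbind(make_ct(paste0("S", i), "2017-10-01", "cvA", "RA", 1, 1, 20 + i / 10),
          make_ct(paste0("S", i), "2017-10-01", "cvA", "RB", 1, 1, 21.5 + i / 10))))
  tab2 <- reference_stability(const, c("RA", "RB"))
  expect_equal(tab2$genorm_m, c(0, 0), tolerance = 1e-12)
  expect_equal(tab2$delta_ct_sd, c(0, 0), tolerance = 1e-12)

  expect_error(reference_stability(const, "RA"), "at least two")
})

test_that("2^-ddCt identities hold: calibrator at 1, one cycle halves expression", {
  ct <- make_fold_ct(c(1, 0.5, 4))
  rel <- delta_delta_ct(ct, "R", "S1")
  cal <- rel[rel$sample_id == "S1", ]
  expect_equal(cal$rel_expr, rep(1, nrow(cal)), tolerance = 1e-9)
  # S2 planted one delta-Ct cycle above calibrator
  expect_equal(unique(rel$rel_expr[rel$sample_id == "S2"]), 0.5,
               tolerance = 1e-9)
  expect_equal(unique(rel$rel_expr[rel$sample_id == "S3"]), 4,
               tolerance = 1e-9)
  # invariance: shifting every Ct of one sample leaves rel_expr unchanged
  shifted <- ct
  shifted$ct[shifted$sample_id == "S3"] <-
    shifted$ct[shifted$sample_id == "S3"] + 2.7
  rel2 <- delta_delta_ct(shifted, "R", "S1")
  expect_equal(rel2$rel_expr, rel$rel_expr, tolerance = 1e-9)
  # log2(rel_expr) is affine in -ddCt with slope 1
  expect_equal(log2(rel$rel_expr),
               -(rel$delta_ct - rel$delta_ct[rel$sample_id == "S1"][1]),
               tolerance = 1e-9)
})

test_that("ddCt errors name missing calibrators and genes", {
  ct <- make_fold_ct(c(1, 2))
  expect_error(delta_delta_ct(ct, "R", "S9"), "calibrator sample 'S9'")
  expect_error(delta_delta_ct(ct, "NOPE", "S1"), "reference gene")
  # calibrator non-detected for a gene detected elsewhere is an error
  nd <- ct
  nd$ct[nd$sample_id == "S1" & nd$gene == "T"] <- NA
  expect_error(delta_delta_ct(nd, "R", "S1"), "T")
  # a gene never detected anywhere is surfaced, not an error
  ct2 <- rbind(ct, make_ct("S1", "2017-10-01", "cvA", "DEAD", 1, 1, NA),
               make_ct("S2", "2017-10-08", "cvA", "DEAD", 1, 1, NA))
  rel <- delta_delta_ct(ct2, "R", "S1")
  expect_equal(attr(rel, "undetected_genes"), "DEAD")
  expect_false("DEAD" %in% rel$gene)
})

test_that("generator inversion: zero-noise Ct tables reproduce planted folds", {
  cfg <- default_sim_config(4)
  cfg$expression$bio_sd <- 0
  cfg$expression$tech_sd <- 0
  sim <- simulate_dataset(cfg)
  rel <- delta_delta_ct(sim$ct, cfg$gene_panel$gene[cfg$gene_panel$archetype == "reference"],
                        sim$truth$calibrator)
  prof <- summarize_profiles(rel)
  truth <- sim$truth$fold
  set.seed(1)
  for (g in sample(dimnames(truth)[[1]][1:40], 8)) {
    for (cv in dimnames(truth)[[3]]) {
      got <- prof$mean_rel_expr[prof$gene == g & prof$cultivar == cv]
      expect_equal(got, unname(truth[g, , cv]), tolerance = 1e-9)
    }
  }
})

test_that("profile summarisation averages technical then biological replicates", {
  # balanced: all replicates equal
  rel <- data.frame(gene = "T", date = as.Date("2017-10-01"), cultivar = "cvA",
                    bio_rep = rep(1:3, each = 2), rel_expr = 5)
  expect_equal(summarize_profiles(rel)$mean_rel_expr, 5)
  # unbalanced worked fixture: tech (2,4) -> bio mean 3; lone tech 5 -> bio 5;
  # cell mean 4, not the flat reaction mean 11/3
  rel2 <- data.frame(gene = "T", date = as.Date("2017-10-01"),
                     cultivar = "cvA", bio_rep = c(1, 1, 2),
                     rel_expr = c(2, 4, 5))
  out <- summarize_profiles(rel2)
  expect_equal(out$mean_rel_expr, 4)
  expect_equal(out$n_bio, 2L)
  # a fully missing biological replicate lowers the count, not the mean
  rel3 <- data.frame(gene = "T", date = as.Date("2017-10-01"),
                     cultivar = "cvA", bio_rep = 1:3,
                     rel_expr = c(6, 8, NA))
  out3 <- summarize_profiles(rel3)
  expect_equal(out3$mean_rel_expr, 7)
  expect_equal(out3$n_bio, 2L)
  # all-missing cell is NA, never zero
  rel4 <- data.frame(gene = "T", date = as.Date("2017-10-01"),
                     cultivar = "cvA", bio_rep = 1:2, rel_expr = NA_real_)
  expect_true(is.na(summarize_profiles(rel4)$mean_rel_expr))
})
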