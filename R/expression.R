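#' Read a qPCR cycle-threshold (Ct) table
#'
#' Expects the long-format header
#' `sample_id,date,cultivar,gene,bio_rep,tech_rep,ct,quality`. An empty or
#' `NA` `ct` field marks a non-detected reaction and is kept as `NA`;
#' quality scores must lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return data.frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  req <- c("sample_id", "date", "cultivar", "gene", "bio_rep", "tech_rep",
           "ct", "quality")
  if (!all(req %in% names(df)))
    stop("Ct CSV must have header: ", paste(req, collapse = ","),
         call. = FALSE)
  df$date <- as.Date(df$date)
  df$ct <- as.numeric(df$ct)
  df$quality <- as.numeric(df$quality)
  if (any(is.na(df$quality)) || any(df$quality < 0 | df$quality > 1))
    stop("quality scores must lie in [0, 1]", call. = FALSE)
  if (any(df$ct <= 0, na.rm = TRUE))
    stop("detected Ct values must be positive", call. = FALSE)
  df
}

#' Write a Ct table as CSV (round-trips through [read_ct_csv()])
#' @param records Ct record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Quality-filter a Ct table by sample and by assay
#'
#' Removes whole samples and whole assays (gene/primer pairs) whose
#' aggregate amplification-quality score falls below the threshold, the way
#' a plate-level quality check discards failed wells' units rather than
#' single reactions. The aggregate is the mean quality of all reactions of
#' the unit, computed on the original table; the removal is the union of
#' failing samples and failing assays.
#'
#' @param records Ct record data.frame (see [read_ct_csv()]).
#' @param threshold quality threshold in `[0, 1]` (default 0.65).
#' @return list with `kept` (surviving records) and `exclusions`
#'   (data.frame `unit_type`, `unit`, `mean_quality`, `reason` naming every
#'   removed sample and assay).
#' @export
qc_filter <- function(records, threshold = 0.65) {
  stopifnot(threshold >= 0, threshold <= 1)
  sample_q <- tapply(records$quality, records$sample_id, mean)
  assay_q <- tapply(records$quality, records$gene, mean)
  bad_samples <- names(sample_q)[sample_q < threshold]
  bad_assays <- names(assay_q)[assay_q < threshold]
  excl <- rbind(
    if (length(bad_samples))
      data.frame(unit_type = "sample", unit = bad_samples,
                 mean_quality = as.numeric(sample_q[bad_samples])),
    if (length(bad_assays))
      data.frame(unit_type = "assay", unit = bad_assays,
                 mean_quality = as.numeric(assay_q[bad_assays])))
  if (is.null(excl))
    excl <- data.frame(unit_type = character(), unit = character(),
                       mean_quality = numeric())
  excl$reason <- if (nrow(excl)) sprintf("mean quality %.3f < threshold %.2f",
                                         excl$mean_quality, threshold)
                 else character()
  kept <- records[!(records$sample_id %in% bad_samples) &
                    !(records$gene %in% bad_assays), , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("quality filtering removed every record: unusable plate",
         call. = FALSE)
  rownames(kept) <- NULL
  rownames(excl) <- NULL
  list(kept = kept, exclusions = excl)
}

# mean Ct per (sample_id, bio_rep, gene) with technical replicates averaged;
# NA (non-detected) reactions are dropped, a unit with no detected reaction
# stays NA
tech_averaged_ct <- function(records) {
  key <- interaction(records$sample_id, records$bio_rep, records$gene,
                     drop = TRUE, sep = "\r")
  agg <- tapply(records$ct, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  df <- data.frame(sample_id = parts[, 1],
                   bio_rep = as.integer(parts[, 2]),
                   gene = parts[, 3],
                   ct = as.numeric(agg),
                   stringsAsFactors = FALSE)
  meta <- unique(records[, c("sample_id", "bio_rep", "date", "cultivar")])
  merge(df, meta, by = c("sample_id", "bio_rep"), sort = FALSE)
}

#' Rank candidate reference genes by expression stability
#'
#' Computes two component stability measures for each candidate reference
#' gene and aggregates their ranks:
#' \describe{
#'   \item{`genorm_m`}{pairwise-variation measure: the mean, over all other
#'     candidates, of the standard deviation across samples of the log2
#'     expression ratio (equivalently the Ct difference), computed on
#'     replicate-averaged sample means.}
#'   \item{`delta_ct_sd`}{comparative delta-Ct measure: the mean standard
#'     deviation of per-biological-replicate Ct differences to every other
#'     candidate.}
#' }
#' The comprehensive rank is the geometric mean of the two per-measure
#' ranks; lower values mean more stable expression.
#'
#' @param records Ct record data.frame.
#' @param candidate_refs character vector (>= 2) of candidate reference
#'   gene names.
#' @param max_missing a candidate missing (non-detected or absent) in more
#'   than this fraction of samples is dropped with a warning (default 0.2).
#' @return data.frame sorted by `comprehensive_rank` with columns `gene`,
#'   `genorm_m`, `delta_ct_sd`, `rank_genorm`, `rank_delta_ct`,
#'   `comprehensive_rank`.
#' @export
reference_stability <- function(records, candidate_refs, max_missing = 0.2) {
  candidate_refs <- unique(as.character(candidate_refs))
  if (length(candidate_refs) < 2L)
    stop("need at least two candidate reference genes", call. = FALSE)
  tav <- tech_averaged_ct(records[records$gene %in% candidate_refs, ,
                                  drop = FALSE])
  units <- unique(tav[, c("sample_id", "bio_rep")])
  n_units <- nrow(units)
  coverage <- vapply(candidate_refs, function(g) {
    sum(!is.na(tav$ct[tav$gene == g])) / n_units
  }, numeric(1))
  drop <- candidate_refs[coverage < 1 - max_missing]
  if (length(drop)) {
    warning("candidate reference gene(s) missing in > ",
            round(100 * max_missing), "% of samples, excluded: ",
            paste(drop, collapse = ", "), call. = FALSE)
    candidate_refs <- setdiff(candidate_refs, drop)
  }
  if (length(candidate_refs) < 2L)
    stop("fewer than two usable candidate reference genes", call. = FALSE)

  # per-biological-replicate Ct matrix (units x genes)
  ct_rep <- sapply(candidate_refs, function(g) {
    m <- merge(units, tav[tav$gene == g, c("sample_id", "bio_rep", "ct")],
               by = c("sample_id", "bio_rep"), all.x = TRUE, sort = FALSE)
    m$ct[match(paste(units$sample_id, units$bio_rep),
               paste(m$sample_id, m$bio_rep))]
  })
  # sample-level Ct matrix (biological replicates averaged)
  samp <- unique(units$sample_id)
  ct_samp <- sapply(candidate_refs, function(g) {
    vapply(samp, function(s) {
      x <- ct_rep[units$sample_id == s, g]
      mean(x, na.rm = TRUE)
    }, numeric(1))
  })

  pair_sd <- function(mat) {
    k <- ncol(mat)
    vapply(seq_len(k), function(j) {
      others <- setdiff(seq_len(k), j)
      mean(vapply(others, function(l)
        stats::sd(mat[, j] - mat[, l], na.rm = TRUE), numeric(1)))
    }, numeric(1))
  }
  genorm_m <- pair_sd(ct_samp)
  delta_ct_sd <- pair_sd(ct_rep)
  rank_g <- rank(genorm_m)
  rank_d <- rank(delta_ct_sd)
  out <- data.frame(gene = candidate_refs,
                    genorm_m = genorm_m,
                    delta_ct_sd = delta_ct_sd,
                    rank_genorm = rank_g,
                    rank_delta_ct = rank_d,
                    comprehensive_rank = sqrt(rank_g * rank_d))
  out <- out[order(out$comprehensive_rank, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' For each biological replicate of each sample, technical replicates are
#' averaged, then `dCt = Ct(target) - mean Ct(reference genes)`. The
#' calibrator sample's dCt (biological replicates averaged) is subtracted
#' per gene to give `ddCt`, and relative expression is `2^-ddCt`, so the
#' calibrator has relative expression 1 for every gene by construction.
#'
#' @param records Ct record data.frame.
#' @param reference_genes character vector of reference gene names (>= 1);
#'   multiple references are combined by the arithmetic mean of their Ct
#'   (the geometric mean of the linear quantities).
#' @param calibrator_sample `sample_id` of the calibrator; it must carry a
#'   detected Ct for every target and reference gene.
#' @return data.frame with one row per (sample, biological replicate,
#'   target gene): `sample_id`, `date`, `cultivar`, `gene`, `bio_rep`,
#'   `delta_ct`, `rel_expr`. Non-detected targets propagate as `NA`.
#' @export
delta_delta_ct <- function(records, reference_genes, calibrator_sample) {
  reference_genes <- as.character(reference_genes)
  if (length(reference_genes) < 1L)
    stop("need at least one reference gene", call. = FALSE)
  if (!all(reference_genes %in% records$gene))
    stop("reference gene(s) absent from records: ",
         paste(setdiff(reference_genes, records$gene), collapse = ", "),
         call. = FALSE)
  if (!calibrator_sample %in% records$sample_id)
    stop("calibrator sample '", calibrator_sample, "' absent from records",
         call. = FALSE)
  tav <- tech_averaged_ct(records)
  refs <- tav[tav$gene %in% reference_genes, , drop = FALSE]
  ref_key <- paste(refs$sample_id, refs$bio_rep)
  ref_mean <- tapply(refs$ct, ref_key, mean)   # NA if any reference missing
  targets <- tav[!(tav$gene %in% reference_genes), , drop = FALSE]
  targets$ref_ct <- as.numeric(ref_mean[paste(targets$sample_id,
                                              targets$bio_rep)])
  if (any(is.na(targets$ref_ct)))
    stop("reference gene Ct missing (non-detected) for sample(s): ",
         paste(unique(targets$sample_id[is.na(targets$ref_ct)]),
               collapse = ", "), call. = FALSE)
  targets$delta_ct <- targets$ct - targets$ref_ct

  # genes never detected anywhere cannot be quantified; they are surfaced
  # as all-missing (attribute "undetected_genes"), never as zeros
  detected_by_gene <- tapply(!is.na(targets$ct), targets$gene, any)
  undetected <- names(detected_by_gene)[!detected_by_gene]
  targets <- targets[!(targets$gene %in% undetected), , drop = FALSE]
  if (nrow(targets) == 0L)
    stop("no target gene with any detected Ct", call. = FALSE)

  cal <- targets[targets$sample_id == calibrator_sample, , drop = FALSE]
  missing_in_cal <- unique(targets$gene)[!unique(targets$gene) %in%
                                           cal$gene[!is.na(cal$delta_ct)]]
  if (length(missing_in_cal))
    stop("calibrator sample lacks a detected Ct for gene(s): ",
         paste(missing_in_cal, collapse = ", "), call. = FALSE)
  cal_dct <- tapply(cal$delta_ct, cal$gene, mean)
  targets$rel_expr <- 2^-(targets$delta_ct -
                            as.numeric(cal_dct[targets$gene]))
  out <- targets[, c("sample_id", "date", "cultivar", "gene", "bio_rep",
                     "delta_ct", "rel_expr")]
  out <- out[order(out$gene, out$date, out$cultivar, out$sample_id,
                   out$bio_rep), ]
  rownames(out) <- NULL
  attr(out, "undetected_genes") <- undetected
  out
}

#' Summarise relative expression into per-timepoint gene profiles
#'
#' Two-stage averaging per (gene, date, cultivar): any remaining technical
#' replicates are first averaged within each biological replicate, then
#' the biological replicate means are averaged — so in unbalanced designs
#' every biological replicate carries equal weight regardless of how many
#' reactions it contributed. Records from [delta_delta_ct()] arrive with
#' technical replicates already averaged, in which case only the second
#' stage applies. Cells whose replicates are all non-detected are reported
#' as `NA` (missing), never as zero.
#'
#' @param rel relative-expression data.frame from [delta_delta_ct()] (one
#'   row per biological replicate), or any data.frame with columns `gene`,
#'   `date`, `cultivar`, `bio_rep`, `rel_expr` and possibly several rows
#'   per biological replicate.
#' @return data.frame of class `expression_profiles` with columns `gene`,
#'   `date`, `cultivar`, `mean_rel_expr`, `n_bio` (surviving biological
#'   replicates per cell).
#' @export
summarize_profiles <- function(rel) {
  req <- c("gene", "date", "cultivar", "bio_rep", "rel_expr")
  if (!all(req %in% names(rel)))
    stop("need columns: ", paste(req, collapse = ", "), call. = FALSE)
  bio_key <- interaction(rel$gene, as.character(rel$date), rel$cultivar,
                         rel$bio_rep, drop = TRUE, sep = "\r")
  bio_mean <- tapply(rel$rel_expr, bio_key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  bp <- do.call(rbind, strsplit(names(bio_mean), "\r", fixed = TRUE))
  key <- interaction(bp[, 1], bp[, 2], bp[, 3], drop = TRUE, sep = "\r")
  vals <- as.numeric(bio_mean)
  mean_expr <- tapply(vals, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  n_bio <- tapply(vals, key, function(x) sum(!is.na(x)))
  parts <- do.call(rbind, strsplit(names(mean_expr), "\r", fixed = TRUE))
  out <- data.frame(gene = parts[, 1],
                    date = as.Date(parts[, 2]),
                    cultivar = parts[, 3],
                    mean_rel_expr = as.numeric(mean_expr),
                    n_bio = as.integer(n_bio),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$cultivar, out$date), ]
  rownames(out) <- NULL
  class(out) <- c("expression_profiles", "data.frame")
  out
}

#' Write expression profiles as a wide CSV (genes x `date|cultivar`)
#' @param profiles an `expression_profiles` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  mat <- profiles_to_matrix(profiles)
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# genes x (cultivar|date) matrix, columns ordered by cultivar then date
profiles_to_matrix <- function(profiles) {
  cvs <- sort(unique(profiles$cultivar))
  dates <- sort(unique(profiles$date))
  genes <- sort(unique(profiles$gene))
  cols <- as.vector(t(outer(cvs, format(dates), paste, sep = "|")))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))
  idx <- cbind(match(profiles$gene, genes),
               match(paste(profiles$cultivar, format(profiles$date),
                           sep = "|"), cols))
  mat[idx] <- profiles$mean_rel_expr
  mat
}
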