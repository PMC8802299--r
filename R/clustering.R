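#' Build the gene x trajectory feature matrix for clustering
#'
#' Turns per-timepoint expression profiles into one feature vector per
#' gene: both cultivars' trajectories are concatenated column-wise
#' (cultivars sorted, dates sorted within cultivar), genes with more than
#' `max_missing` missing cells are dropped and logged, remaining gaps are
#' linearly interpolated along time within each cultivar block (ends carry
#' the nearest observed value), and rows are z-scored when `standardize`
#' is set so that trajectory shape rather than amplitude drives the
#' clustering. Constant rows standardize to all zeros.
#'
#' @param profiles an `expression_profiles` data.frame from
#'   [summarize_profiles()], or any data.frame with columns `gene`, `date`,
#'   `cultivar`, `mean_rel_expr`.
#' @param standardize z-score each gene's feature vector (default TRUE).
#' @param max_missing drop genes with more than this fraction of missing
#'   cells (default 0.3).
#' @return Numeric matrix, genes as rows, `cultivar|date` columns; dropped
#'   genes listed in attribute `dropped`.
#' @export
build_feature_matrix <- function(profiles, standardize = TRUE,
                                 max_missing = 0.3) {
  mat <- profiles_to_matrix(profiles)
  if (nrow(mat) == 0L) stop("no genes in profiles", call. = FALSE)
  frac_na <- rowMeans(is.na(mat))
  dropped <- rownames(mat)[frac_na > max_missing]
  mat <- mat[frac_na <= max_missing, , drop = FALSE]
  if (nrow(mat) == 0L)
    stop("all genes exceed the missing-cell limit", call. = FALSE)
  # interpolate within each cultivar's block of columns
  cv_of_col <- sub("\\|.*$", "", colnames(mat))
  for (cv in unique(cv_of_col)) {
    cols <- which(cv_of_col == cv)
    for (i in seq_len(nrow(mat))) {
      y <- mat[i, cols]
      if (anyNA(y) && any(!is.na(y)))
        mat[i, cols] <- stats::approx(seq_along(y), y, xout = seq_along(y),
                                      method = "linear", rule = 2)$y
    }
  }
  if (anyNA(mat))
    stop("gene(s) entirely missing within one cultivar block: ",
         paste(rownames(mat)[apply(is.na(mat), 1, any)], collapse = ", "),
         call. = FALSE)
  if (standardize) {
    mu <- rowMeans(mat)
    sd <- apply(mat, 1, stats::sd)
    mat <- (mat - mu) / ifelse(sd > 0, sd, 1)
    mat[sd == 0, ] <- 0                     # zero-variance guard
  }
  attr(mat, "dropped") <- dropped
  mat
}

# deterministic sub-seeds for the restarts, derived from the master seed
derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Best-of-n k-means clustering of expression trajectories
#'
#' Runs k-means `n_starts` times from distinct random starting assignments
#' (sub-seeds derived deterministically from `seed`) and keeps the run with
#' the smallest total within-cluster sum of squares. Cluster labels are
#' arbitrary in k-means; here they are reported in a canonical order, by
#' the time index at which each centroid attains its maximum, so runs are
#' comparable. Squared Euclidean distance throughout.
#'
#' @param features numeric matrix from [build_feature_matrix()].
#' @param k number of clusters, `2 <= k < nrow(features)`.
#' @param n_starts random restarts (default 25).
#' @param seed master seed; the whole result is reproducible given it.
#' @param iter_max iteration cap per run (default 100).
#' @return list of class `kmeans_best` with elements `k`, `assignments`
#'   (named integer vector, gene -> cluster), `centroids` (k x p matrix),
#'   `total_wss`, `per_run_wss` (length `n_starts`), `seed`.
#' @export
kmeans_best_of_n <- function(features, k, n_starts = 25, seed = 1,
                             iter_max = 100) {
  stopifnot(is.matrix(features), n_starts >= 1)
  if (!(k >= 2 && k < nrow(features)))
    stop("require 2 <= k < number of genes (", nrow(features), ")",
         call. = FALSE)
  subseeds <- derive_subseeds(seed, n_starts)
  runs <- vector("list", n_starts)
  wss <- rep(Inf, n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(subseeds[s])
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(features, centers = k, nstart = 1,
                                     iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) {
      runs[[s]] <- fit
      wss[s] <- fit$tot.withinss
    }
  }
  if (all(!is.finite(wss)))
    stop("every k-means restart failed (empty cluster); lower k",
         call. = FALSE)
  best <- runs[[which.min(wss)]]
  # canonical label order: by centroid time-of-maximum, ties by first gene
  ord <- order(apply(best$centers, 1, which.max),
               apply(best$centers, 1, max), decreasing = FALSE)
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[best$cluster]
  names(assignments) <- rownames(features)
  structure(list(k = k,
                 assignments = assignments,
                 centroids = best$centers[ord, , drop = FALSE],
                 total_wss = min(wss),
                 per_run_wss = wss,
                 seed = seed),
            class = "kmeans_best")
}

#' @export
print.kmeans_best <- function(x, ...) {
  cat(sprintf("<kmeans_best> k=%d, %d genes, total WSS %.3f (best of %d)\n",
              x$k, length(x$assignments), x$total_wss,
              length(x$per_run_wss)))
  invisible(x)
}

#' Within-cluster sum of squares across candidate cluster numbers
#'
#' Computes the best-of-n WSS for each `k` in `k_min:k_max` and suggests an
#' elbow as the `k` maximizing the second difference of the WSS curve. The
#' final choice of `k` is left to the user. `k = 1` reports the total sum
#' of squared deviations from the grand centroid.
#'
#' @inheritParams kmeans_best_of_n
#' @param k_min,k_max range of cluster numbers (`k_min >= 1`,
#'   `k_max < nrow(features)`).
#' @return data.frame `k`, `total_wss`, with attribute `elbow` (suggested
#'   k, `NA` when the range is too short to form a second difference).
#' @export
wss_curve <- function(features, k_min = 1, k_max = 10, n_starts = 25,
                      seed = 1) {
  if (!(k_min >= 1 && k_min <= k_max && k_max < nrow(features)))
    stop("require 1 <= k_min <= k_max < number of genes", call. = FALSE)
  ks <- k_min:k_max
  wss <- vapply(ks, function(k) {
    if (k == 1) sum(sweep(features, 2, colMeans(features))^2)
    else kmeans_best_of_n(features, k, n_starts = n_starts,
                          seed = seed + k)$total_wss
  }, numeric(1))
  out <- data.frame(k = ks, total_wss = wss)
  elbow <- NA_integer_
  if (length(ks) >= 3) {
    d2 <- diff(wss, differences = 2)        # at interior ks
    elbow <- ks[which.max(d2) + 1L]
  }
  attr(out, "elbow") <- elbow
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label permutation), 0 the expected
#' agreement of random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
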