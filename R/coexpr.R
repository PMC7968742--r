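#' Log-transform counts and average replicates per condition
#'
#' Scales counts by library size factors, takes `log2(scaled + 1)` and
#' averages replicate columns within each genotype x sex x channel condition.
#'
#' @param ct A `count_table`.
#' @param sf Size factors; recomputed if `NULL`.
#' @return Numeric matrix, genes x conditions (condition labels
#'   `genotype.sex.channel`).
#' @export
transform_counts <- function(ct, sf = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(sf)) sf <- size_factors(ct)
  lg <- log2(sweep(ct$counts, 2, sf, "/") + 1)
  cond <- interaction(ct$design$genotype, ct$design$sex, ct$design$channel,
                      drop = TRUE)
  out <- sapply(levels(cond), function(l)
    rowMeans(lg[, cond == l, drop = FALSE]))
  rownames(out) <- rownames(ct$counts)
  out
}

#' Standardize expression profiles to Z-scores
#'
#' Per gene, subtracts the mean and divides by the standard deviation across
#' conditions. Genes with zero variance get an all-zero profile and are
#' flagged in the `"constant"` attribute.
#'
#' @param profiles Genes x conditions matrix (>= 2 columns).
#' @return Matrix of Z-scores with attribute `constant` (logical per gene).
#' @export
zscore <- function(profiles) {
  stopifnot(ncol(profiles) >= 2)
  mu <- rowMeans(profiles)
  sd_ <- apply(profiles, 1, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  z <- (profiles - mu) / ifelse(const, 1, sd_)
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

# k-means++ initial centers (deterministic given the RNG state)
kmeanspp_centers <- function(Z, k) {
  n <- nrow(Z)
  centers <- matrix(NA_real_, k, ncol(Z))
  idx <- sample.int(n, 1)
  centers[1, ] <- Z[idx, ]
  d2 <- rowSums((Z - matrix(centers[1, ], n, ncol(Z), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- Z[idx, ]
    d2 <- pmin(d2, rowSums((Z - matrix(centers[j, ], n, ncol(Z),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of Z-score profiles
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ initial centers,
#' keeping the best of `n_init` restarts by total within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param Z Genes x conditions matrix of standardized profiles.
#' @param k Number of clusters (2 <= k < number of genes).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 25).
#' @return List of class `cluster_model`: `k`, `assignments` (named integer
#'   vector), `centroids` (k x conditions), `wss` (total within-cluster sum
#'   of squares), `seed`.
#' @export
kmeans_fit <- function(Z, k, seed = 1L, n_init = 25L) {
  stopifnot(k >= 2, k < nrow(Z))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(Z, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(Z, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  assignments <- stats::setNames(best$cluster, rownames(Z))
  structure(list(k = nrow(best$centers), assignments = assignments,
                 centroids = best$centers, wss = best$tot.withinss,
                 seed = seed),
            class = "cluster_model")
}

#' Within-cluster sum of squares across a range of k
#'
#' Runs [kmeans_fit()] with the same restart protocol for each candidate `k`
#' to locate the elbow of the WSS curve.
#'
#' @param Z Standardized profile matrix.
#' @param k_range Integer vector of candidate cluster counts.
#' @inheritParams kmeans_fit
#' @return `data.frame` with columns `k`, `wss`.
#' @export
elbow_curve <- function(Z, k_range = 2:20, seed = 1L, n_init = 25L) {
  wss <- vapply(k_range, function(k) {
    if (k >= nrow(Z)) return(0)
    kmeans_fit(Z, k, seed = seed, n_init = n_init)$wss
  }, numeric(1))
  data.frame(k = k_range, wss = wss)
}

#' Per-cluster centroid expression profiles
#'
#' Mean member Z-profile per cluster and condition, with member counts.
#'
#' @param model A `cluster_model`.
#' @param Z The matrix the model was fitted on.
#' @return List: `centroids` (k x conditions matrix of member means) and
#'   `sizes` (genes per cluster).
#' @export
centroid_profiles <- function(model, Z) {
  stopifnot(inherits(model, "cluster_model"))
  cl <- model$assignments[rownames(Z)]
  cents <- t(sapply(sort(unique(cl)), function(g)
    colMeans(Z[cl == g, , drop = FALSE])))
  rownames(cents) <- paste0("M", sort(unique(cl)))
  sizes <- as.integer(table(cl))
  names(sizes) <- paste0("M", sort(unique(cl)))
  list(centroids = cents, sizes = sizes)
}
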