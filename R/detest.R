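#' Median-of-ratios library size factors
#'
#' For each sample, the factor is the median across reference genes of the
#' ratio of its count to the gene's geometric mean across samples; reference
#' genes are those with strictly positive counts in every sample. When no
#' such gene exists the function falls back to total-count ratios with a
#' warning.
#'
#' @param x A `count_table` or numeric count matrix.
#' @return Named positive numeric vector, one factor per sample, normalized
#'   to geometric mean 1.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  allpos <- rowSums(m <= 0) == 0
  if (!any(allpos)) {
    warning("no gene with all-positive counts; using total-count ratios")
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf)))
    return(stats::setNames(sf, colnames(m)))
  }
  lm_ <- log(m[allpos, , drop = FALSE])
  geo <- rowMeans(lm_)
  sf <- apply(lm_, 2, function(col) exp(stats::median(col - geo)))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Filter genes by library-size-scaled abundance
#'
#' Keeps genes with at least `min_samples` samples whose scaled count
#' (count / size factor) strictly exceeds `min_scaled`.
#'
#' @param ct A `count_table`.
#' @param min_scaled Scaled-count threshold (default 10, strict `>`).
#' @param min_samples Number of qualifying samples required (default 3).
#' @param sf Optional precomputed size factors.
#' @return The filtered `count_table`, with the kept gene ids in attribute
#'   `"kept"`.
#' @export
filter_genes <- function(ct, min_scaled = 10, min_samples = 3, sf = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(sf)) sf <- size_factors(ct)
  scaled <- sweep(ct$counts, 2, sf, "/")
  keep <- rowSums(scaled > min_scaled) >= min_samples
  out <- subset_count_table(ct, genes = keep)
  attr(out, "kept") <- rownames(ct$counts)[keep]
  out
}

# ---- negative-binomial GLM engine -------------------------------------------

# IRLS fit of an NB GLM with log link and fixed dispersion phi
# (variance = mu + phi*mu^2). Fractional y are accepted: the quasi-score is
# identical to the NB score evaluated at continuous y.
nb_glm_fit <- function(y, X, offset = rep(0, length(y)), phi,
                       maxit = 50L, tol = 1e-10) {
  beta <- tryCatch(qr.solve(X, log(pmax(y, 0.5)) - offset),
                   error = function(e) rep(0, ncol(X)))
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; conv <- TRUE; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  w <- mu / (1 + phi * mu)
  cov <- tryCatch(solve(t(X * w) %*% X),
                  error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, cov = cov, converged = conv)
}

#' Estimate per-gene NB dispersions with a mean trend
#'
#' Method-of-moments estimation: within each design group the sample variance
#' in the size-factor-scaled counts estimates `m + phi*m^2`. Per-gene
#' estimates are pooled within bins of log mean abundance using
#' `phi_bin = sum(s^2 - m) / sum(m^2)` and interpolated back to genes, which
#' averages out the large sampling noise of small-replicate variance
#' estimates while retaining any mean-dispersion trend.
#'
#' @param counts Count matrix (genes x samples).
#' @param group Factor of length `ncol(counts)` defining replicate groups.
#' @param sf Size factors (default recomputed from `counts`).
#' @param method `"trend"` (binned pooled estimate, default), `"common"`
#'   (single pooled value), or `"gene"` (raw per-gene moments).
#' @param n_bins Number of abundance bins for the trend.
#' @param floor Minimum dispersion returned.
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, group, sf = size_factors(counts),
                                method = c("trend", "common", "gene"),
                                n_bins = 20L, floor = 1e-8) {
  method <- match.arg(method)
  scaled <- sweep(counts, 2, sf, "/")
  group <- as.factor(group)
  lv <- levels(group)
  s2 <- matrix(0, nrow(counts), length(lv))
  mg <- matrix(0, nrow(counts), length(lv))
  df <- numeric(length(lv))
  for (k in seq_along(lv)) {
    cols <- which(group == lv[k])
    sub <- scaled[, cols, drop = FALSE]
    mg[, k] <- rowMeans(sub)
    s2[, k] <- if (length(cols) > 1) apply(sub, 1, stats::var) else 0
    df[k] <- max(length(cols) - 1L, 0L)
  }
  usable <- df > 0
  w <- df[usable] / sum(df[usable])
  s2p <- drop(s2[, usable, drop = FALSE] %*% w)
  mp <- drop(mg[, usable, drop = FALSE] %*% w)
  gene_phi <- pmax((s2p - mp) / pmax(mp^2, 1e-8), floor)
  if (method == "gene") return(gene_phi)
  pooled <- function(idx) {
    num <- sum(s2p[idx] - mp[idx]); den <- sum(mp[idx]^2)
    if (den <= 0) return(floor)
    max(num / den, floor)
  }
  if (method == "common") return(rep(pooled(seq_along(mp)), length(mp)))
  ok <- mp > 0
  lmu <- log(pmax(mp, 1e-8))
  br <- stats::quantile(lmu[ok], probs = seq(0, 1, length.out = n_bins + 1L))
  br <- unique(br)
  if (length(br) < 3L) return(rep(pooled(which(ok)), length(mp)))
  bin <- cut(lmu, br, include.lowest = TRUE)
  centers <- tapply(lmu, bin, mean)
  phis <- vapply(levels(bin), function(b) pooled(which(bin == b & ok)),
                 numeric(1))
  good <- !is.na(centers) & !is.na(phis)
  out <- stats::approx(centers[good], phis[good], xout = lmu, rule = 2)$y
  pmax(out, floor)
}

#' Negative-binomial Wald contrasts
#'
#' Fits a per-gene NB generalized linear model (log link, log size factors as
#' offsets, one shared dispersion per gene across all groups) and tests a
#' linear combination of the coefficients with a Wald statistic against the
#' standard normal. P-values are Benjamini-Hochberg adjusted across genes and
#' calls are significant at `padj < alpha`. Fold changes are reported in log2.
#'
#' @param ct A filtered `count_table` (see [filter_genes()]).
#' @param design_formula Model formula over design-sheet columns, e.g.
#'   `~ group`.
#' @param contrast Either a numeric vector over the model coefficients or the
#'   name of a single coefficient.
#' @param sf Size factors; recomputed if `NULL`.
#' @param dispersion `"trend"`, `"common"`, `"gene"`, or a numeric vector /
#'   scalar of known dispersions.
#' @param group Factor used for dispersion estimation; defaults to the
#'   interaction of all design variables in the formula.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return `data.frame` of class `contrast_result`: `gene`, `log2FC`, `SE`,
#'   `stat`, `p`, `padj`, `significant`, `direction`.
#' @export
fit_contrast <- function(ct, design_formula, contrast, sf = NULL,
                         dispersion = "trend", group = NULL, alpha = 0.05) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(sf)) sf <- size_factors(ct)
  X <- stats::model.matrix(design_formula, data = ct$design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X))
      stop("coefficient '", contrast, "' not in the design matrix")
    L <- as.numeric(colnames(X) == contrast)
  } else {
    L <- as.numeric(contrast)
    if (length(L) != ncol(X)) stop("contrast length must match coefficients")
  }
  if (is.null(group)) {
    vars <- all.vars(design_formula)
    group <- interaction(ct$design[vars], drop = TRUE)
  }
  phi <- if (is.numeric(dispersion)) {
    rep_len(dispersion, nrow(ct$counts))
  } else {
    estimate_dispersion(ct$counts, group, sf = sf, method = dispersion)
  }
  offset <- log(sf)
  n <- nrow(ct$counts)
  est <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- ct$counts[i, ]
    if (all(y == 0)) next
    f <- nb_glm_fit(y, X, offset, phi[i])
    est[i] <- sum(L * f$beta)
    v <- drop(t(L) %*% f$cov %*% L)
    se[i] <- if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  }
  stat <- est / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[is.na(p)] <- 1
  flagged_zero <- rowSums(ct$counts) == 0
  p[flagged_zero] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    gene = rownames(ct$counts),
    log2FC = est / log(2), SE = se / log(2), stat = stat, p = p, padj = padj,
    significant = padj < alpha,
    direction = ifelse(is.na(est) | est == 0, 0L, as.integer(sign(est))),
    stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Pairwise group contrast
#'
#' Convenience wrapper fitting a one-factor cell-means NB model on a subset
#' of samples and testing `log(mean[level_num]) - log(mean[level_den]) = 0`.
#'
#' @param ct A `count_table`.
#' @param samples Logical or integer index of samples to use.
#' @param group Factor (over the selected samples) defining the cells.
#' @param level_num,level_den Numerator and denominator levels of the fold
#'   change.
#' @inheritParams fit_contrast
#' @return A `contrast_result` with `log2FC = log2(level_num / level_den)`.
#' @export
de_pairwise <- function(ct, samples, group, level_num, level_den, sf = NULL,
                        dispersion = "trend", alpha = 0.05) {
  sub <- subset_count_table(ct, samples = samples)
  group <- droplevels(as.factor(group))
  stopifnot(length(group) == ncol(sub$counts),
            all(c(level_num, level_den) %in% levels(group)))
  if (is.null(sf)) sf <- size_factors(sub)
  sub$design$.grp <- group
  X_lv <- levels(group)
  L <- as.numeric(X_lv == level_num) - as.numeric(X_lv == level_den)
  fit_contrast(sub, ~ 0 + .grp, L, sf = sf, dispersion = dispersion,
               group = group, alpha = alpha)
}

#' Species, sex and species-by-sex contrasts
#'
#' Fits one NB cell-means model over the four parental species x sex groups
#' and reports three contrasts per gene: the species main effect (CNI vs CBR
#' averaged over sexes), the sex main effect (male vs female averaged over
#' species) and the species-by-sex interaction (difference of the sex effects
#' between species). Each contrast family is FDR-adjusted separately.
#'
#' @param ct A `count_table` with parental `total` samples for both sexes.
#' @inheritParams fit_contrast
#' @return Named list of three `contrast_result`s: `species`, `sex`,
#'   `interaction`.
#' @export
species_sex_fit <- function(ct, sf = NULL, dispersion = "trend", alpha = 0.05) {
  d <- ct$design
  sel <- d$genotype %in% c("CBR", "CNI") & d$channel == "total"
  sub <- subset_count_table(ct, samples = sel)
  dd <- sub$design
  if (length(unique(dd$sex)) < 2L) stop("both sexes required")
  grp <- factor(paste(dd$genotype, dd$sex, sep = "."),
                levels = c("CBR.female", "CBR.male", "CNI.female", "CNI.male"))
  if (any(is.na(grp)) || nlevels(droplevels(grp)) < 4L)
    stop("all four species x sex groups required")
  sub$design$.grp <- grp
  if (is.null(sf)) sf <- size_factors(sub)
  contrasts <- list(
    species = c(-0.5, -0.5, 0.5, 0.5),      # CNI - CBR, averaged over sex
    sex = c(-0.5, 0.5, -0.5, 0.5),          # male - female, averaged over species
    interaction = c(1, -1, -1, 1))          # (CNI.m - CNI.f) - (CBR.m - CBR.f)
  lapply(contrasts, function(L)
    fit_contrast(sub, ~ 0 + .grp, L, sf = sf, dispersion = dispersion,
                 group = grp, alpha = alpha))
}

#' Joint parental/allelic model: P, A and the trans effect T
#'
#' Fits one NB model per gene over four groups — the two parental totals and
#' the two F1 allele channels — and reports three contrasts: the parental
#' log2 ratio `P = CNI_parent - CBR_parent`, the allelic ratio
#' `A = CNI_allele - CBR_allele` (allele-specific expression, the cis
#' estimator), and the trans effect `T = P - A`, a Wald test of equality of
#' the two ratios. Because all three come from the same cell-means fit the
#' identity `T = P - A` holds exactly at the estimate level. A single
#' per-gene dispersion is shared across the four groups, and each contrast
#' family is FDR-adjusted separately.
#'
#' @param ct A `count_table` with parental totals and F1 allele channels.
#' @param sex Sex context to analyze (default `"female"`).
#' @inheritParams fit_contrast
#' @return Named list of three `contrast_result`s: `P`, `A`, `T`.
#' @export
regulatory_contrasts <- function(ct, sex = "female", sf = NULL,
                                 dispersion = "trend", alpha = 0.05) {
  d <- ct$design
  sel <- d$sex == sex &
    ((d$genotype %in% c("CBR", "CNI") & d$channel == "total") |
     (d$genotype == "F1" & d$channel %in% c("allele_CBR", "allele_CNI")))
  sub <- subset_count_table(ct, samples = sel)
  dd <- sub$design
  grp <- factor(ifelse(dd$channel == "total", paste0(dd$genotype, "_parent"),
                       sub("allele_", "", dd$channel, fixed = TRUE) |>
                         paste0("_allele")),
                levels = c("CBR_parent", "CNI_parent", "CBR_allele", "CNI_allele"))
  if (nlevels(droplevels(grp)) < 4L)
    stop("parental totals and both F1 allele channels are required")
  sub$design$.grp <- grp
  if (is.null(sf)) sf <- size_factors(sub)
  contrasts <- list(
    P = c(-1, 1, 0, 0),
    A = c(0, 0, -1, 1),
    T = c(-1, 1, 1, -1))   # (CNIp - CBRp) - (CNIa - CBRa)
  lapply(contrasts, function(L)
    fit_contrast(sub, ~ 0 + .grp, L, sf = sf, dispersion = dispersion,
                 group = grp, alpha = alpha))
}

#' Wald test for trans effects
#'
#' Convenience front end to [regulatory_contrasts()] returning only the
#' trans-effect family: the Wald test of equality between the parental and
#' allelic log2 ratios, whose estimate is `T = P - A`.
#'
#' @inheritParams regulatory_contrasts
#' @return A `contrast_result` for the trans effect.
#' @export
trans_test <- function(ct, sex = "female", sf = NULL, dispersion = "trend",
                       alpha = 0.05) {
  regulatory_contrasts(ct, sex = sex, sf = sf, dispersion = dispersion,
                       alpha = alpha)$T
}

#' Write contrast results to TSV
#'
#' @param res A `contrast_result`.
#' @param path Output path.
#' @param contrast Label written in a `contrast` column.
#' @param header Optional provenance comment line.
#' @return Invisibly, the path.
#' @export
write_contrast <- function(res, path, contrast = "contrast", header = NULL) {
  out <- cbind(gene = res$gene, contrast = contrast,
               res[, c("log2FC", "SE", "stat", "p", "padj")])
  write_tsv_with_header(out, path, header)
}
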