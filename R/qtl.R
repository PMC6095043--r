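# Cis-association mapping: xQTL (SNP -> molecular feature) and eQTM/eQTH
# (epigenetic peak -> mRNA), with permutation-based feature-level
# significance, BH FDR, Storey's pi1 and best-SNP selection.
#
# Coordinates are 1-based inclusive. Cis windows are symmetric around the
# feature anchor (TSS for genes, peak center for marks) and truncated at 1.

#' Define a symmetric cis window around a feature anchor
#'
#' @param chrom chromosome of the feature.
#' @param pos anchor position in base pairs (TSS for genes, peak center for
#'   epigenetic marks), 1-based.
#' @param w window half-width in base pairs (> 0); the window is
#'   `[max(1, pos - w), pos + w]`.
#' @param feature optional feature identifier carried through.
#' @return data.frame with columns `feature`, `chrom`, `start`, `end`.
#' @examples
#' define_cis_window("1", 100000, 50000)  # [50000, 150000]
#' define_cis_window("1", 3000, 5000)     # left-truncated at 1
#' @export
define_cis_window <- function(chrom, pos, w, feature = NA_character_) {
  if (!is.numeric(w) || any(w <= 0)) stop("w must be > 0", call. = FALSE)
  if (any(pos < 1)) stop("pos must be >= 1", call. = FALSE)
  data.frame(feature = feature, chrom = chrom,
             start = pmax(1, pos - w), end = pos + w,
             stringsAsFactors = FALSE)
}

#' Simple linear-regression association between two sample vectors
#'
#' Least-squares slope of `y` on `x` with the two-sided t-test p-value,
#' computed on complete pairs.
#'
#' @param y response sample vector.
#' @param x predictor sample vector (non-constant).
#' @return list with `beta`, `se`, `statistic`, `p_value`, `n`.
#' @examples
#' marginal_association(1:10, (1:10) * 2)
#' @export
marginal_association <- function(y, x) {
  ok <- complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0)
    stop("predictor is constant; association undefined", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  rss <- sum((yc - beta * xc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se == 0) sign(beta) * Inf else beta / se
  list(beta = beta, se = se, statistic = tval,
       p_value = 2 * pt(-abs(tval), df = n - 2), n = n)
}

## correlation p-value for a common sample size
.cor_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-tval, df = n - 2)
}

#' Permutation p-value for the best association among candidates
#'
#' The observed statistic is the best nominal p-value of `y` against each
#' candidate row of `X`; permutations shuffle `y` only, and the empirical
#' p-value is `(1 + #{perm best p <= observed}) / (n_perm + 1)`.
#'
#' @param y response sample vector.
#' @param X candidates x samples numeric matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @return list with `p_nominal` (best nominal p), `p_empirical`,
#'   `best` (row index of the best candidate), `r_best` (its correlation),
#'   `n_perm`.
#' @export
permutation_min_p <- function(y, X, n_perm = 1000, seed = NULL) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(is.matrix(X), ncol(X) == length(y))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  ys <- scale(y)[, 1]
  Xs <- scale(t(X))            # samples x candidates
  Xs[, is.na(colSums(Xs))] <- 0  # constant candidates contribute r = 0
  r_obs <- drop(crossprod(Xs, ys)) / (n - 1)
  best <- which.max(abs(r_obs))
  stat_obs <- abs(r_obs[best])
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- matrix(ys[perm_idx], nrow = n)
  Rn <- abs(crossprod(Xs, Yp)) / (n - 1)   # candidates x n_perm
  stat_null <- apply(Rn, 2, max)
  list(p_nominal = .cor_p(r_obs[best], n),
       p_empirical = (1 + sum(stat_null >= stat_obs)) / (n_perm + 1),
       best = unname(best),
       r_best = unname(r_obs[best]),
       n_perm = n_perm)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `pvals`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Storey's estimate of the fraction of true alternatives (pi1)
#'
#' pi0 is estimated as #\{p > lambda\} / (m (1 - lambda)) over a lambda
#' grid. The default point estimate is the median of the grid values
#' (robust and low-variance when signal p-values concentrate near zero);
#' `method = "smoother"` instead extrapolates a smoothing spline to the
#' largest lambda (the Storey-Tibshirani smoother, less biased when the
#' alternative has mass at moderate p but noisier in the tail).
#' pi1 = 1 - pi0, clipped to \[0, 1\]; used as a replication rate between
#' association studies.
#'
#' @param pvals numeric p-values (>= 100 recommended).
#' @param lambda grid of lambda values in (0, 1).
#' @param method `"median"` (default) or `"smoother"`.
#' @return object of class `replication_stat`: list with `pi1`, `pi0`,
#'   `pi0_lambda`, `lambda`, `n`.
#' @export
storey_pi1 <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05),
                       method = c("median", "smoother")) {
  method <- match.arg(method)
  pvals <- pvals[!is.na(pvals)]
  m <- length(pvals)
  if (m == 0) stop("no p-values supplied", call. = FALSE)
  stopifnot(all(lambda > 0 & lambda < 1), length(lambda) >= 4)
  pi0_lambda <- vapply(lambda, function(l) sum(pvals > l) / (m * (1 - l)),
                       numeric(1))
  pi0 <- if (method == "median") {
    median(pi0_lambda)
  } else {
    fit <- smooth.spline(lambda, pi0_lambda, df = 3)
    predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi1 = 1 - pi0, pi0 = pi0, pi0_lambda = pi0_lambda,
                 lambda = lambda, n = m),
            class = "replication_stat")
}

## candidate lookup: rows of `info` (chrom, pos) inside a window, ordered by
## (pos, id) so that downstream which.max tie-breaks deterministically
.candidates_in_window <- function(info, chrom, start, end) {
  hit <- info$chrom == chrom & info$pos >= start & info$pos <= end
  idx <- which(hit)
  idx[order(info$pos[idx], info[[1]][idx])]
}

#' Map cis quantitative trait loci for one omics layer
#'
#' For each feature, SNPs whose position falls within `w` base pairs of the
#' feature anchor are tested; feature-level significance comes from the
#' permutation scheme of [permutation_min_p()] and FDR control from BH
#' q-values on the permutation p-values across features. Missing dosages
#' are mean-imputed per SNP. Features with no candidate SNP are reported
#' with `n_tested = 0`, not dropped.
#'
#' @param omics features x samples numeric matrix.
#' @param genotypes a `genotype_matrix` (see [simulate_genotypes()]) or a
#'   list with `dosage` (SNPs x samples) and `info` (snp, chrom, pos).
#' @param annotations data.frame with columns `feature`, `chrom`, `pos`.
#' @param w cis window half-width in base pairs (50 kb for mRNA and H3K9ac,
#'   5 kb for DNA methylation by convention).
#' @param n_perm permutations per feature (default 1000).
#' @param fdr FDR level for the significance flag (default 0.05).
#' @param seed optional integer seed; each feature uses a derived stream.
#' @param qnorm quantile-normalize each feature before testing (default
#'   TRUE, the conventional guard against outliers).
#' @param min_samples minimum shared samples required (default 30).
#' @return data.frame of class `qtl_result`: feature, variant, beta, r,
#'   nominal_p, perm_p, qvalue, n_tested, significant.
#' @export
map_cis_qtl <- function(omics, genotypes, annotations, w,
                        n_perm = 1000, fdr = 0.05, seed = NULL,
                        qnorm = TRUE, min_samples = 30) {
  stopifnot(is.matrix(omics))
  dosage <- genotypes$dosage; ginfo <- genotypes$info
  shared <- intersect(colnames(omics), colnames(dosage))
  if (length(shared) < min_samples)
    stop("fewer than ", min_samples, " shared samples", call. = FALSE)
  omics <- omics[, shared, drop = FALSE]
  dosage <- dosage[, shared, drop = FALSE]
  # mean-impute missing dosages per SNP
  if (anyNA(dosage)) {
    mu <- rowMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 1]]
  }
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  rows <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    feat <- annotations$feature[i]
    if (!feat %in% rownames(omics)) next
    wd <- define_cis_window(annotations$chrom[i], annotations$pos[i], w, feat)
    cand <- .candidates_in_window(ginfo, wd$chrom, wd$start, wd$end)
    if (length(cand) == 0) {
      rows[[i]] <- data.frame(feature = feat, variant = NA_character_,
                              beta = NA_real_, r = NA_real_,
                              nominal_p = NA_real_, perm_p = NA_real_,
                              n_tested = 0L, stringsAsFactors = FALSE)
      next
    }
    y <- omics[feat, ]
    if (qnorm) y <- quantile_normalize(y)
    pm <- permutation_min_p(y, dosage[cand, , drop = FALSE], n_perm = n_perm,
                            seed = if (is.null(base_seed)) NULL
                                   else (base_seed + i) %% .Machine$integer.max)
    x_best <- dosage[cand[pm$best], ]
    beta <- pm$r_best * sd(y) / max(sd(x_best), .Machine$double.eps)
    rows[[i]] <- data.frame(feature = feat,
                            variant = ginfo$snp[cand[pm$best]],
                            beta = beta, r = pm$r_best,
                            nominal_p = pm$p_nominal, perm_p = pm$p_empirical,
                            n_tested = length(cand), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$qvalue <- NA_real_
  tested <- res$n_tested > 0
  res$qvalue[tested] <- bh_fdr(res$perm_p[tested])
  res$significant <- !is.na(res$qvalue) & res$qvalue <= fdr
  class(res) <- c("qtl_result", class(res))
  res
}

#' Map expression-associated epigenetic peaks (eQTM / eQTH)
#'
#' Tests every gene against the epigenetic peaks whose center lies within
#' `w` base pairs of the gene's TSS. Two significance layers are applied:
#' peak-level BH across all gene-peak pairs, and gene-level permutation
#' p-values (best peak per gene) BH-adjusted across genes. A pair is flagged
#' significant only if both layers pass `fdr`. The correlation sign is
#' retained for regulation-sign annotation.
#'
#' @param expression genes x samples matrix.
#' @param epigenome peaks x samples matrix.
#' @param expr_annot data.frame `feature`, `chrom`, `pos` (TSS) for genes.
#' @param epi_annot data.frame `feature`, `chrom`, `pos` (center) for peaks.
#' @param w window half-width (default 1 Mb).
#' @param n_perm,fdr,seed,qnorm,min_samples as in [map_cis_qtl()].
#' @return data.frame of class `eqtx_result`: gene, peak, r, p_pair,
#'   q_pair, p_gene, q_gene, significant.
#' @export
map_eqtx <- function(expression, epigenome, expr_annot, epi_annot,
                     w = 1e6, n_perm = 1000, fdr = 0.05, seed = NULL,
                     qnorm = TRUE, min_samples = 30) {
  stopifnot(is.matrix(expression), is.matrix(epigenome))
  shared <- intersect(colnames(expression), colnames(epigenome))
  if (length(shared) < min_samples)
    stop("fewer than ", min_samples, " shared samples", call. = FALSE)
  expression <- expression[, shared, drop = FALSE]
  epigenome <- epigenome[, shared, drop = FALSE]
  if (qnorm) {
    expression <- quantile_normalize(expression)
    epigenome <- quantile_normalize(epigenome)
  }
  n <- length(shared)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  pair_rows <- list(); gene_rows <- list()
  for (i in seq_len(nrow(expr_annot))) {
    gene <- expr_annot$feature[i]
    if (!gene %in% rownames(expression)) next
    wd <- define_cis_window(expr_annot$chrom[i], expr_annot$pos[i], w, gene)
    cand <- .candidates_in_window(epi_annot, wd$chrom, wd$start, wd$end)
    if (length(cand) == 0) next
    peaks <- epi_annot$feature[cand]
    peaks <- peaks[peaks %in% rownames(epigenome)]
    if (length(peaks) == 0) next
    X <- epigenome[peaks, , drop = FALSE]
    pm <- permutation_min_p(expression[gene, ], X, n_perm = n_perm,
                            seed = if (is.null(base_seed)) NULL
                                   else (base_seed + i) %% .Machine$integer.max)
    ys <- scale(expression[gene, ])[, 1]
    Xs <- scale(t(X))
    Xs[, is.na(colSums(Xs))] <- 0
    r_all <- drop(crossprod(Xs, ys)) / (n - 1)
    pair_rows[[i]] <- data.frame(gene = gene, peak = peaks, r = r_all,
                                 p_pair = .cor_p(r_all, n),
                                 stringsAsFactors = FALSE)
    gene_rows[[i]] <- data.frame(gene = gene, p_gene = pm$p_empirical,
                                 stringsAsFactors = FALSE)
  }
  if (length(pair_rows) == 0) {
    out <- data.frame(gene = character(0), peak = character(0), r = numeric(0),
                      p_pair = numeric(0), q_pair = numeric(0),
                      p_gene = numeric(0), q_gene = numeric(0),
                      significant = logical(0))
    class(out) <- c("eqtx_result", class(out))
    return(out)
  }
  pairs <- do.call(rbind, pair_rows)
  genes <- do.call(rbind, gene_rows)
  genes$q_gene <- bh_fdr(genes$p_gene)
  pairs$q_pair <- bh_fdr(pairs$p_pair)
  pairs$p_gene <- genes$p_gene[match(pairs$gene, genes$gene)]
  pairs$q_gene <- genes$q_gene[match(pairs$gene, genes$gene)]
  pairs$significant <- pairs$q_pair <= fdr & pairs$q_gene <= fdr
  rownames(pairs) <- NULL
  class(pairs) <- c("eqtx_result", class(pairs))
  pairs
}

#' Best SNP per feature from a QTL result table
#'
#' Returns the significant features' best variants as a named character
#' vector (feature -> variant). The best SNP is the one with the smallest
#' nominal p-value in the feature's window; exact ties resolve to the
#' lowest genomic position then lexicographic id (applied during mapping).
#' Features without a significant SNP are absent from the map.
#'
#' @param results a [map_cis_qtl()] result.
#' @return named character vector, feature -> variant id.
#' @export
best_snp_per_feature <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  keep <- results$significant %in% TRUE
  setNames(results$variant[keep], results$feature[keep])
}
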