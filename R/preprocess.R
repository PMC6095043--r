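# Normalization and covariate-removal transforms applied to omics matrices
# before association mapping and network inference.

#' Convert methylation Beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Values at or beyond the open interval (0, 1)
#' are clipped to `[eps, 1 - eps]` before the transform; values outside
#' \[0, 1\] are rejected.
#'
#' @param beta numeric vector of Beta methylation fractions in \[0, 1\].
#' @param eps clipping epsilon (default 1e-6).
#' @return numeric vector of M-values.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) stop("beta must be numeric", call. = FALSE)
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad))
    stop("beta values outside [0, 1]: ", paste(head(beta[bad]), collapse = ", "),
         call. = FALSE)
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to the Beta scale
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector of M-values.
#' @return numeric vector of Beta fractions in (0, 1).
#' @export
m_to_beta <- function(m) {
  stopifnot(is.numeric(m))
  1 / (1 + 2^(-m))
}

#' Rank-based inverse-normal (quantile) normalization
#'
#' Per feature, values are replaced by standard-normal quantiles of their
#' ranks using the offset (r - 0.5) / n; ties receive average ranks. Any
#' strictly monotone transform of a feature leaves the output unchanged.
#' A constant feature maps to an all-zero row with a warning.
#'
#' @param x numeric matrix (features x samples) or a numeric vector.
#' @return object of the same shape; feature means are approximately 0.
#' @examples
#' quantile_normalize(c(1, 2, 3))  # qnorm(c(1, 3, 5) / 6)
#' @export
quantile_normalize <- function(x) {
  qn_vec <- function(v) {
    if (anyNA(v)) stop("missing values are not supported", call. = FALSE)
    r <- rank(v, ties.method = "average")
    qnorm((r - 0.5) / length(v))
  }
  if (is.matrix(x)) {
    if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
    const <- apply(x, 1, function(v) length(unique(v)) == 1L)
    if (any(const))
      warning(sum(const), " constant feature(s) mapped to all-zero rows")
    out <- t(apply(x, 1, qn_vec))
    dimnames(out) <- dimnames(x)
    out
  } else {
    if (length(unique(x)) == 1L) warning("constant feature mapped to zeros")
    qn_vec(x)
  }
}

#' Remove covariates from a matrix by linear regression
#'
#' Replaces each feature by its least-squares residuals on the covariates
#' (an intercept is always included), so residuals are orthogonal to every
#' covariate. The operation is a projection and therefore idempotent.
#'
#' @param x numeric matrix, features x samples.
#' @param covariates numeric matrix, covariates x samples (may have zero
#'   rows, in which case features are simply mean-centered).
#' @return matrix of residuals, same shape as `x`.
#' @examples
#' x <- matrix(rnorm(20), 2, 10)
#' cv <- matrix(rnorm(10), 1, 10)
#' r <- residualize(x, cv)
#' max(abs(r %*% t(cv)))  # ~ 0
#' @export
residualize <- function(x, covariates = NULL) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = 0, ncol = n)
  if (is.vector(covariates)) covariates <- matrix(covariates, nrow = 1)
  stopifnot(ncol(covariates) == n)
  design <- cbind(`(intercept)` = 1, t(covariates))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("covariates are collinear; redundant: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  Q <- qr.Q(qrd)
  x - tcrossprod(x %*% Q, Q)
}

#' Estimate hidden covariate factors by truncated SVD
#'
#' A variance-capturing factor decomposition of the feature-standardized
#' matrix, serving as the hidden-covariate model whose per-feature composite
#' is consumed by LRN node construction. Factors are ordered by explained
#' variance.
#'
#' @param x numeric matrix, features x samples.
#' @param k number of factors; `k = 0` yields an empty model whose
#'   composites are zero.
#' @return object of class `hidden_factor_model`: list with `factors`
#'   (k x samples), `weights` (features x k), `k`, and `sdev` (singular
#'   values / sqrt(n - 1)).
#' @examples
#' x <- outer(rnorm(30), rnorm(20)) + matrix(rnorm(600, sd = 0.01), 30)
#' fm <- estimate_hidden_factors(x, 1)
#' @export
estimate_hidden_factors <- function(x, k) {
  stopifnot(is.matrix(x), is.numeric(k), length(k) == 1)
  k <- as.integer(k)
  n <- ncol(x)
  if (k >= min(nrow(x), n))
    stop("k must be smaller than min(features, samples)", call. = FALSE)
  if (k <= 0) {
    return(structure(list(factors = matrix(0, 0, n, dimnames = list(NULL, colnames(x))),
                          weights = matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL)),
                          k = 0L, sdev = numeric(0)),
                     class = "hidden_factor_model"))
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  sv <- svd(z, nu = k, nv = k)
  factors <- t(sv$v[, seq_len(k), drop = FALSE])
  rownames(factors) <- sprintf("F%d", seq_len(k))
  colnames(factors) <- colnames(x)
  weights <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(weights) <- rownames(x)
  colnames(weights) <- rownames(factors)
  structure(list(factors = factors, weights = weights, k = k,
                 sdev = sv$d[seq_len(k)] / sqrt(n - 1)),
            class = "hidden_factor_model")
}

#' Composite hidden covariate for one feature
#'
#' The feature-specific combination C_j = sum_i w_ij * F_i of the hidden
#' factors, one value per sample. This is the value carried by the C-class
#' nodes of an LRN.
#'
#' @param model a [estimate_hidden_factors()] result.
#' @param feature feature identifier (row name of the modeled matrix).
#' @return named numeric vector, one value per sample.
#' @export
composite_covariate <- function(model, feature) {
  stopifnot(inherits(model, "hidden_factor_model"))
  if (model$k == 0L)
    return(setNames(rep(0, ncol(model$factors)), colnames(model$factors)))
  if (!feature %in% rownames(model$weights))
    stop("unknown feature: ", feature, call. = FALSE)
  drop(model$weights[feature, , drop = FALSE] %*% model$factors)
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' The per-sample statistic d_i = 1 - mean Spearman correlation of sample i
#' with all other samples; samples with d_i outside 1.5 x the interquartile
#' range beyond the quartiles of d are flagged.
#'
#' @param x numeric matrix, features x samples (>= 4 samples).
#' @return object of class `outlier_report`: list with `d` (named statistic
#'   vector), `threshold` (lower, upper), and `flagged` (sample ids).
#' @export
detect_outliers <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 4) stop("need at least 4 samples", call. = FALSE)
  C <- suppressWarnings(cor(x, method = "spearman"))
  C[!is.finite(C)] <- 0
  d <- 1 - (colSums(C) - 1) / (ncol(x) - 1)
  names(d) <- colnames(x)
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  threshold <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  flagged <- names(d)[d < threshold[1] | d > threshold[2]]
  if (is.null(flagged)) flagged <- which(d < threshold[1] | d > threshold[2])
  structure(list(d = d, threshold = threshold, flagged = flagged),
            class = "outlier_report")
}
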