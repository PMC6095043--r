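# Decomposable Gaussian network scores.
#
# Default is the BGe score: the closed-form marginal likelihood of a child
# given its parents under a conjugate normal-Wishart prior. It is
# score-equivalent (Markov-equivalent DAGs receive equal total scores) and
# decomposable, so the total score of a DAG is the sum of family scores.
# Hyperparameters: alpha_mu = 1, alpha_w = p + 2, prior scale T = t * I with
# t = alpha_mu * (alpha_w - p - 1) / (alpha_mu + 1), on column-standardized
# data (unit variance), so the prior expects unit marginal variances.
#
# A Gaussian BIC score is available as an alternative (not score-equivalent
# in finite samples for all priors, but asymptotically consistent).

## log multivariate gamma
.lmvgamma <- function(l, a) {
  if (l == 0) return(0)
  l * (l - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(l)) / 2))
}

## Precompute the sufficient matrices for BGe scoring.
.bge_setup <- function(values, am = 1, aw = NULL) {
  x <- as.matrix(values)
  n <- nrow(x); p <- ncol(x)
  if (is.null(aw)) aw <- p + 2
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  z <- scale(x, center = TRUE, scale = sdv)
  tscale <- am * (aw - p - 1) / (am + 1)
  R <- diag(tscale, p) + crossprod(z)  # prior mean = sample mean
  dimnames(R) <- list(colnames(x), colnames(x))
  list(R = R, n = n, p = p, am = am, aw = aw, tscale = tscale,
       cache = new.env(parent = emptyenv()))
}

## log p(D_Y) for a node subset Y (integer indices); cached
.bge_lp <- function(setup, Y) {
  l <- length(Y)
  if (l == 0) return(0)
  Y <- sort(Y)
  key <- paste(Y, collapse = ",")
  hit <- setup$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- setup$n; p <- setup$p; am <- setup$am; aw <- setup$aw
  ldR <- as.numeric(determinant(setup$R[Y, Y, drop = FALSE], logarithm = TRUE)$modulus)
  ldT <- l * log(setup$tscale)
  lp <- -l * n / 2 * log(pi) + l / 2 * (log(am) - log(am + n)) +
    .lmvgamma(l, (n + aw - p + l) / 2) - .lmvgamma(l, (aw - p + l) / 2) +
    (aw - p + l) / 2 * ldT - (n + aw - p + l) / 2 * ldR
  setup$cache[[key]] <- lp
  lp
}

.bge_family <- function(setup, child, parents) {
  .bge_lp(setup, c(parents, child)) - .bge_lp(setup, parents)
}

.bic_family <- function(values, child, parents) {
  n <- nrow(values)
  y <- values[, child]
  X <- cbind(1, values[, parents, drop = FALSE])
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, .Machine$double.eps)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - 0.5 * (length(parents) + 2) * log(n)
}

#' Log family score of a child given a parent set
#'
#' The decomposable score contribution of one node: under `"bge"` the
#' closed-form Gaussian marginal log-likelihood of the child given its
#' parents (conjugate normal-Wishart prior); under `"bic"` the Gaussian
#' log-likelihood penalized by BIC. Total DAG score is the sum of family
#' scores over all nodes.
#'
#' @param node_set an [lrn_node_set()] or a samples x nodes numeric matrix.
#' @param child child node name.
#' @param parents character vector of parent node names (possibly empty).
#' @param score `"bge"` (default) or `"bic"`.
#' @return log score (numeric scalar).
#' @examples
#' v <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
#' family_score(v, "b", "a") + family_score(v, "a", character(0))
#' @export
family_score <- function(node_set, child, parents = character(0),
                         score = c("bge", "bic")) {
  score <- match.arg(score)
  values <- if (inherits(node_set, "lrn_node_set")) node_set$values else node_set
  stopifnot(is.matrix(values), child %in% colnames(values),
            all(parents %in% colnames(values)), !child %in% parents)
  if (nrow(values) <= length(parents) + 3)
    stop("need more samples than parents + 3", call. = FALSE)
  idx <- setNames(seq_len(ncol(values)), colnames(values))
  if (score == "bge") {
    setup <- .bge_setup(values)
    .bge_family(setup, idx[[child]], unname(idx[parents]))
  } else {
    .bic_family(values, child, parents)
  }
}

## Build the per-child score lookup tables consumed by the samplers.
## allowed: list (per child index) of integer vectors of allowed parent
## indices. Returns list of numeric vectors indexed by local bitmask + 1.
.score_tables <- function(values, allowed, score = "bge", max_parents = Inf) {
  p <- ncol(values)
  setup <- if (score == "bge") .bge_setup(values) else NULL
  tables <- vector("list", p)
  for (j in seq_len(p)) {
    aj <- allowed[[j]]
    k <- length(aj)
    if (k > 12)
      stop("more than 12 allowed parents for one node; network too large",
           call. = FALSE)
    tab <- numeric(2^k)
    for (mask in 0:(2^k - 1)) {
      pa <- aj[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
      if (length(pa) > max_parents) {
        tab[mask + 1] <- -Inf
      } else if (score == "bge") {
        tab[mask + 1] <- .bge_family(setup, j, pa)
      } else {
        tab[mask + 1] <- .bic_family(values, j, pa)
      }
    }
    tables[[j]] <- tab
  }
  tables
}
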