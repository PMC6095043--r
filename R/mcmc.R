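# Structure MCMC over mask-constrained DAGs, the exact enumeration oracle,
# and the three-state consensus network.

## allowed-parent index lists (0-based) from a child x parent logical mask
.allowed_list <- function(mask) {
  p <- nrow(mask)
  lapply(seq_len(p), function(j) which(mask[j, ]) - 1L)
}

.check_mask <- function(node_set, mask) {
  nodes <- colnames(node_set$values)
  stopifnot(is.matrix(mask), nrow(mask) == length(nodes),
            ncol(mask) == length(nodes))
  if (any(diag(mask))) stop("mask allows self-edges", call. = FALSE)
  roots <- is_snp_class(node_set$classes) | is_covariate_class(node_set$classes)
  if (any(mask[roots, ]))
    stop("mask allows parents for SNP or covariate nodes", call. = FALSE)
  invisible(mask)
}

#' Posterior edge frequencies by constrained structure MCMC
#'
#' Metropolis-Hastings sampling over mask-respecting DAGs targeting
#' P(G | X) proportional to P(X | G) under a uniform structure prior.
#' Proposals mix single-edge additions, deletions and reversals with the
#' new-edge-reversal (REV) move, which reverses an existing edge and
#' resamples the parent sets of both endpoints from their score-weighted
#' conditionals (better mixing across edge orientations). Acyclicity and
#' the allowed-parent mask are enforced on every proposal. Edge frequencies
#' are tallied from every post-burn-in iteration (no thinning).
#'
#' @param node_set an [lrn_node_set()].
#' @param mask allowed-parent mask (default [allowed_parent_mask()]).
#' @param n_steps number of MCMC steps (default 75,000).
#' @param burn_in fraction of initial steps discarded (default 0.10).
#' @param seed optional integer seed.
#' @param score `"bge"` or `"bic"` family score.
#' @param rev_prob probability of proposing a REV move (default 1/15).
#' @param max_parents optional cap on parent-set size (default unlimited).
#' @param trace_every record the log score every this many steps (0 = off).
#' @return object of class `lrn_edge_freq`: list with `freq` (parent x
#'   child frequency matrix), `n_samples_used`, `acceptance_rate`,
#'   `log_score` (final / max / trace), `n_steps`, `classes`.
#' @export
structure_mcmc <- function(node_set, mask = allowed_parent_mask(node_set),
                           n_steps = 75000, burn_in = 0.10, seed = NULL,
                           score = c("bge", "bic"), rev_prob = 1 / 15,
                           max_parents = Inf, trace_every = 500) {
  stopifnot(inherits(node_set, "lrn_node_set"))
  score <- match.arg(score)
  .check_mask(node_set, mask)
  if (!is.null(seed)) set.seed(seed)
  values <- node_set$values
  nodes <- colnames(values)
  p <- length(nodes)
  allowed0 <- .allowed_list(mask)
  tables <- .score_tables(values, lapply(allowed0, `+`, 1L),
                          score = score, max_parents = max_parents)
  res <- .lrn_mcmc_cpp(p, allowed0, tables, as.integer(n_steps),
                       burn_in, rev_prob, as.integer(trace_every))
  freq <- res$freq
  dimnames(freq) <- list(parent = nodes, child = nodes)
  if (res$acceptance_rate == 0 && any(mask))
    warning("no accepted moves; log-score trace: ",
            paste(signif(res$trace, 6), collapse = ", "))
  structure(list(freq = freq,
                 n_samples_used = res$n_used,
                 acceptance_rate = res$acceptance_rate,
                 log_score = list(final = res$log_score_final,
                                  max = res$log_score_max,
                                  trace = res$trace),
                 n_steps = n_steps,
                 classes = node_set$classes),
            class = "lrn_edge_freq")
}

#' @export
print.lrn_edge_freq <- function(x, ...) {
  cat("LRN posterior edge frequencies (", x$n_samples_used,
      " sampled DAGs, acceptance ", signif(x$acceptance_rate, 3), ")\n", sep = "")
  print(round(x$freq, 3))
  invisible(x)
}

#' Exact posterior edge probabilities by DAG enumeration
#'
#' Enumerates every mask-respecting DAG, normalizes the posterior under the
#' uniform structure prior, and marginalizes edge probabilities exactly.
#' Intended as the small-network oracle for [structure_mcmc()]; refuses node
#' sets whose enumeration would be too large (more than 6 constrained
#' nodes, or too many parent-set combinations).
#'
#' @inheritParams structure_mcmc
#' @return object of class `lrn_edge_freq` with exact `freq`, plus
#'   `log_evidence`, `map_dag` (highest-scoring adjacency matrix) and
#'   `n_dags`.
#' @export
exhaustive_posterior <- function(node_set, mask = allowed_parent_mask(node_set),
                                 score = c("bge", "bic"), max_parents = Inf) {
  stopifnot(inherits(node_set, "lrn_node_set"))
  score <- match.arg(score)
  .check_mask(node_set, mask)
  values <- node_set$values
  nodes <- colnames(values)
  free <- rowSums(mask) > 0
  if (sum(free) > 6)
    stop("more than 6 nodes with allowed parents; enumeration refused",
         call. = FALSE)
  allowed0 <- .allowed_list(mask)
  tables <- .score_tables(values, lapply(allowed0, `+`, 1L),
                          score = score, max_parents = max_parents)
  res <- .lrn_exhaustive_cpp(length(nodes), allowed0, tables)
  freq <- res$freq
  dimnames(freq) <- list(parent = nodes, child = nodes)
  map_dag <- res$best
  dimnames(map_dag) <- dimnames(freq)
  structure(list(freq = freq,
                 log_evidence = res$log_evidence,
                 map_dag = map_dag,
                 best_log_score = res$best_log_score,
                 n_dags = res$n_dags,
                 classes = node_set$classes),
            class = c("lrn_exact_posterior", "lrn_edge_freq"))
}

#' Consensus directed network from posterior edge frequencies
#'
#' For every unordered node pair the most frequent of the three states
#' (i regulates j, j regulates i, independent) is kept, where the
#' independence frequency is `1 - f[i,j] - f[j,i]`. Exact ties resolve to
#' independence. Should the resulting digraph contain a cycle (possible in
#' principle, since pairs are voted independently), the lowest-frequency
#' edge inside each strongly connected component is dropped until the graph
#' is acyclic, with a warning.
#'
#' @param freqs an `lrn_edge_freq` (or a plain parent x child frequency
#'   matrix).
#' @return an igraph DAG with vertex attribute `class` (when available) and
#'   edge attribute `frequency`.
#' @examples
#' f <- matrix(c(0, 0, 0.7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' consensus_network(f)
#' @export
consensus_network <- function(freqs) {
  f <- if (inherits(freqs, "lrn_edge_freq")) freqs$freq else freqs
  stopifnot(is.matrix(f), nrow(f) == ncol(f))
  nodes <- rownames(f)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(f)))
  edges <- NULL
  for (i in seq_len(nrow(f) - 1)) {
    for (j in seq(i + 1, ncol(f))) {
      fij <- f[i, j]; fji <- f[j, i]
      find <- 1 - fij - fji
      if (fij > fji && fij > find) {
        edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[j],
                                         frequency = fij))
      } else if (fji > fij && fji > find) {
        edges <- rbind(edges, data.frame(from = nodes[j], to = nodes[i],
                                         frequency = fji))
      }
      # ties (including two-way direction ties) resolve to independence
    }
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0),
                                   frequency = numeric(0)) else edges,
    directed = TRUE, vertices = data.frame(name = nodes))
  cls <- if (inherits(freqs, "lrn_edge_freq")) freqs$classes else NULL
  if (!is.null(cls)) igraph::V(g)$class <- unname(cls[nodes])
  # break any voting-induced cycles: drop the weakest edge in each cycle
  while (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- which(comp$csize > 1)[1]
    vids <- which(comp$membership == cyc)
    # edges fully inside the cyclic component
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    inside <- which(ends[, 1] %in% vids & ends[, 2] %in% vids)
    fr <- igraph::E(g)$frequency[inside]
    drop <- inside[order(fr, inside)][1]
    warning("consensus voting produced a cycle; dropping lowest-frequency edge")
    g <- igraph::delete_edges(g, drop)
  }
  g
}
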