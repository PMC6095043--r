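# Upstream / downstream / independent labels from consensus DAGs, the
# direct-edge rule for upstream genes, cross-phenotype consensus and
# regulation-sign annotation.

#' Classify the relation between two nodes of a DAG
#'
#' Directed-path reachability: if a path a -> ... -> b exists, `a` is
#' `upstream` of `b`; if a path b -> ... -> a exists, `downstream`;
#' otherwise `independent`. Acyclicity guarantees the first two cases are
#' exclusive.
#'
#' @param dag an igraph DAG (e.g. from [consensus_network()]).
#' @param a,b vertex names.
#' @return one of `"upstream"`, `"downstream"`, `"independent"`.
#' @examples
#' g <- igraph::graph_from_literal("g_m" -+ "m" -+ "e")
#' classify_relation(g, "m", "e")
#' @export
classify_relation <- function(dag, a, b) {
  stopifnot(igraph::is_igraph(dag))
  nodes <- igraph::V(dag)$name
  if (!a %in% nodes || !b %in% nodes)
    stop("unknown node: ", paste(setdiff(c(a, b), nodes), collapse = ", "),
         call. = FALSE)
  d_ab <- igraph::distances(dag, v = a, to = b, mode = "out")[1, 1]
  if (is.finite(d_ab) && d_ab > 0) return("upstream")
  d_ba <- igraph::distances(dag, v = b, to = a, mode = "out")[1, 1]
  if (is.finite(d_ba) && d_ba > 0) return("downstream")
  "independent"
}

#' Relation labels of all source nodes against a reference node
#'
#' Applies [classify_relation()] to every source (by default all epigenetic
#' mark nodes, identified by vertex class or name prefix) against the
#' reference (by default the mRNA node).
#'
#' @param dag an igraph DAG with named vertices.
#' @param sources character vector of source vertex names; default all
#'   `m`/`h`-class vertices.
#' @param reference reference vertex name; default the `e`-class vertex.
#' @param phenotype_id optional phenotype context recorded in the output.
#' @return data.frame: `source`, `reference`, `phenotype`, `label`.
#' @export
relation_table <- function(dag, sources = NULL, reference = NULL,
                           phenotype_id = NA_character_) {
  stopifnot(igraph::is_igraph(dag))
  nodes <- igraph::V(dag)$name
  cls <- igraph::vertex_attr(dag, "class")
  if (is.null(cls)) cls <- node_class(nodes)
  if (is.null(reference)) reference <- nodes[cls == "e"][1]
  if (is.null(sources)) sources <- nodes[cls %in% c("m", "h")]
  if (is.na(reference)) stop("no reference node found", call. = FALSE)
  if (length(sources) == 0)
    return(data.frame(source = character(0), reference = character(0),
                      phenotype = character(0), label = character(0)))
  data.frame(source = sources, reference = reference,
             phenotype = phenotype_id,
             label = vapply(sources, classify_relation, character(1),
                            dag = dag, b = reference),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call genes upstream, downstream or independent of a phenotype
#'
#' A gene is `upstream` of the phenotype if and only if its mRNA node has a
#' direct outgoing edge to the phenotype node (the direct-edge rule);
#' `downstream` if a directed path leads from the phenotype to the mRNA
#' node; `independent` otherwise (e.g. when both are children of a shared
#' anchor without a connecting path).
#'
#' @param dags a named list of consensus DAGs (one per gene, igraph), or a
#'   single igraph DAG.
#' @param mrna_node,phenotype_node vertex names of the mRNA and phenotype
#'   nodes (defaults locate them by vertex class, falling back to names
#'   `"e"` and `"p"`).
#' @return data.frame: `gene`, `label`.
#' @export
call_upstream_genes <- function(dags, mrna_node = NULL, phenotype_node = NULL) {
  if (igraph::is_igraph(dags)) dags <- list(gene = dags)
  stopifnot(length(dags) > 0)
  one <- function(dag) {
    nodes <- igraph::V(dag)$name
    cls <- igraph::vertex_attr(dag, "class")
    if (is.null(cls)) cls <- node_class(nodes)
    e <- if (is.null(mrna_node)) nodes[cls == "e"][1] else mrna_node
    p <- if (is.null(phenotype_node)) nodes[cls == "p"][1] else phenotype_node
    if (is.na(e) || is.na(p) || !e %in% nodes || !p %in% nodes)
      stop("DAG must contain one mRNA and one phenotype node", call. = FALSE)
    if (igraph::are_adjacent(dag, e, p) &&
        p %in% igraph::neighbors(dag, e, mode = "out")$name) return("upstream")
    d <- igraph::distances(dag, v = p, to = e, mode = "out")[1, 1]
    if (is.finite(d) && d > 0) return("downstream")
    "independent"
  }
  genes <- names(dags)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_along(dags))
  data.frame(gene = genes,
             label = vapply(dags, one, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-phenotype consensus of relation labels
#'
#' Keeps the (source, reference, label) triples whose identical label is
#' observed in at least `min_support` phenotype contexts; the support count
#' is recorded. With `min_support = 1` this is the union of all tables.
#' At most one label per ordered pair is ever returned (the best-supported
#' one; ties drop the pair).
#'
#' @param tables list of [relation_table()] data.frames, one per phenotype
#'   context.
#' @param min_support minimum number of agreeing contexts (default 3, the
#'   "at least three of four" rule).
#' @return data.frame: `source`, `reference`, `label`, `support`.
#' @export
consensus_across_phenotypes <- function(tables, min_support = 3) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (length(tables) < min_support)
    stop("fewer phenotype contexts than min_support", call. = FALSE)
  all_t <- do.call(rbind, lapply(tables, function(t)
    t[, c("source", "reference", "label")]))
  agg <- stats::aggregate(list(support = rep(1L, nrow(all_t))),
                          by = all_t[, c("source", "reference", "label")],
                          FUN = sum)
  agg <- agg[agg$support >= min_support, , drop = FALSE]
  # guarantee a single label per ordered pair: strictly best-supported label
  # wins; support ties drop the pair
  key <- paste(agg$source, agg$reference, sep = "\r")
  keep <- rep(TRUE, nrow(agg))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    sup <- agg$support[rows]
    keep[rows] <- FALSE
    if (max(sup) > sort(sup, decreasing = TRUE)[2])
      keep[rows[which.max(sup)]] <- TRUE
  }
  agg <- agg[keep, , drop = FALSE]
  rownames(agg) <- NULL
  agg[order(agg$source, agg$reference), , drop = FALSE]
}

#' Annotate the regulation sign of upstream relations
#'
#' Upstream sources with a negative attached correlation are `suppressor`s,
#' positive ones `activator`s; non-upstream relations get `"n/a"`.
#'
#' @param label character vector of relation labels.
#' @param correlation signed correlation statistic (e.g. the `r` column of a
#'   [map_eqtx()] table), recycled against `label`.
#' @return character vector in `{"activator", "suppressor", "n/a"}`.
#' @examples
#' sign_of_regulation(c("upstream", "upstream", "independent"),
#'                    c(-0.4, 0.4, -0.9))
#' @export
sign_of_regulation <- function(label, correlation) {
  stopifnot(length(label) == length(correlation) || length(correlation) == 1)
  correlation <- rep_len(correlation, length(label))
  out <- rep("n/a", length(label))
  up <- label == "upstream"
  out[up & correlation < 0] <- "suppressor"
  out[up & correlation > 0] <- "activator"
  out
}
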