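# Typed node sets for per-gene local regulatory networks, and the allowed-
# parent mask that encodes the causal-anchor constraints:
#   - SNP nodes have only outgoing edges (causal anchors);
#   - parent menus per class: P(e) in {g_e, m, h, p, C_e},
#     P(m) in {g_m, e, h, p, C_m}, P(h) in {g_h, m, e, p, C_h},
#     P(p) in {g_e, g_m, g_h, m, h, e};
#   - an anchor SNP may only parent its own mark (or the mRNA it tags) and
#     the phenotype; composite covariates only parent their own feature.

CLASS_ORDER <- c("p", "e", "m", "h", "g_e", "g_m", "g_h", "C_e", "C_m", "C_h")

#' Construct an LRN node set
#'
#' Collects the per-node sample vectors for one gene's local regulatory
#' network. Non-genetic nodes (phenotype, mRNA, marks, covariates) are
#' expected on a quantile-normalized scale; [build_node_set()] performs this
#' normalization when assembling from mapping results.
#'
#' @param values samples x nodes numeric matrix, column names are node
#'   names. Names must follow the class conventions of [node_class()]
#'   unless `classes` is given.
#' @param classes optional named character vector of node classes.
#' @param anchors named character vector mapping each SNP node to the node
#'   it anchors (its mark, or the mRNA node for `g_e`).
#' @param cov_targets named character vector mapping each covariate node to
#'   the node it feeds.
#' @param gene gene identifier.
#' @param phenotype_id phenotype identifier.
#' @param require_anchors enforce that every epigenetic node has an anchor
#'   SNP (the LRN inclusion rule; default TRUE). Disable only for
#'   anchor-free comparison runs.
#' @return object of class `lrn_node_set` with elements `values`, `classes`,
#'   `anchors`, `cov_targets`, `gene`, `phenotype_id`.
#' @examples
#' v <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("g_m", "m", "e")))
#' v[, "g_m"] <- rbinom(100, 2, 0.3)
#' ns <- lrn_node_set(v, anchors = c(g_m = "m"))
#' @export
lrn_node_set <- function(values, classes = NULL, anchors = character(0),
                         cov_targets = character(0), gene = "gene",
                         phenotype_id = "phenotype", require_anchors = TRUE) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  nodes <- colnames(values)
  if (is.null(classes)) classes <- setNames(node_class(nodes), nodes)
  stopifnot(all(nodes %in% names(classes)))
  classes <- classes[nodes]
  if (anyNA(values) || any(!is.finite(values)))
    stop("node values must be finite", call. = FALSE)
  if (sum(classes == "e") != 1)
    stop("node set must contain exactly one mRNA (e) node", call. = FALSE)
  if (sum(classes == "p") > 1)
    stop("node set may contain at most one phenotype node", call. = FALSE)
  snps <- nodes[is_snp_class(classes)]
  if (!all(snps %in% names(anchors)))
    stop("every SNP node needs an anchor target", call. = FALSE)
  marks <- nodes[classes %in% c("m", "h")]
  unanchored <- setdiff(marks, anchors)
  if (require_anchors && length(unanchored) > 0)
    stop("epigenetic nodes without an anchor SNP: ",
         paste(unanchored, collapse = ", "),
         " (only SNP-associated marks enter an LRN)", call. = FALSE)
  if (!all(names(cov_targets) %in% nodes) || !all(cov_targets %in% nodes))
    stop("covariate targets must name nodes in the set", call. = FALSE)
  # canonical node order: by class, then name
  ord <- order(match(classes, CLASS_ORDER), nodes)
  values <- values[, ord, drop = FALSE]
  classes <- classes[ord]
  structure(list(values = values, classes = classes, anchors = anchors,
                 cov_targets = cov_targets, gene = gene,
                 phenotype_id = phenotype_id),
            class = "lrn_node_set")
}

#' @export
print.lrn_node_set <- function(x, ...) {
  cat("LRN node set for", x$gene, "(phenotype:", x$phenotype_id, ")\n")
  cat("  ", nrow(x$values), "samples,", ncol(x$values), "nodes:\n")
  cat("  ", paste(sprintf("%s[%s]", colnames(x$values), x$classes),
                  collapse = " "), "\n")
  invisible(x)
}

#' Allowed-parent mask for an LRN node set
#'
#' Boolean matrix `allowed[child, parent]` encoding the structural
#' constraints: SNPs and covariates are roots; each class draws parents
#' from its menu only; anchor SNPs parent their own node and the phenotype;
#' covariates parent only their target feature; no self-edges.
#'
#' @param node_set an [lrn_node_set()].
#' @return logical matrix, rows = children, columns = parents.
#' @export
allowed_parent_mask <- function(node_set) {
  stopifnot(inherits(node_set, "lrn_node_set"))
  nodes <- colnames(node_set$values)
  cls <- node_set$classes
  anchors <- node_set$anchors
  covt <- node_set$cov_targets
  p <- length(nodes)
  mask <- matrix(FALSE, p, p, dimnames = list(child = nodes, parent = nodes))
  for (ch in nodes) {
    for (pa in nodes) {
      if (ch == pa) next
      ok <- switch(cls[[ch]],
        e = (cls[[pa]] == "g_e" && anchors[[pa]] == ch) ||
            cls[[pa]] %in% c("m", "h", "p") ||
            (cls[[pa]] == "C_e" && covt[[pa]] == ch),
        m = (cls[[pa]] == "g_m" && anchors[[pa]] == ch) ||
            cls[[pa]] %in% c("e", "h", "p") ||
            (cls[[pa]] == "C_m" && covt[[pa]] == ch),
        h = (cls[[pa]] == "g_h" && anchors[[pa]] == ch) ||
            cls[[pa]] %in% c("m", "e", "p") ||
            (cls[[pa]] == "C_h" && covt[[pa]] == ch),
        p = cls[[pa]] %in% c("g_e", "g_m", "g_h", "m", "h", "e"),
        FALSE)  # SNP and covariate nodes are roots
      mask[ch, pa] <- isTRUE(ok)
    }
  }
  mask
}

#' Assemble an LRN node set from mapping results
#'
#' Implements the per-gene variable selection: the mRNA node and its best
#' eQTL SNP, every expression-associated epigenetic mark that itself has a
#' QTL (marks without a QTL anchor are excluded), the anchor SNPs, the
#' per-feature composite hidden covariates, and the phenotype. Non-genetic
#' node values are quantile-normalized before structure learning.
#'
#' By default a gene is eligible only if its mRNA has an eQTL SNP and at
#' least one SNP-associated epigenetic mark survives selection
#' (`require = "both"`); `require = "any"` relaxes this to either condition.
#' Ineligible genes raise a condition of class `lrn_ineligible_gene`.
#'
#' @param gene gene identifier (row of `expression`).
#' @param phenotype named numeric vector of phenotype values per sample.
#' @param expression genes x samples matrix.
#' @param genotypes a `genotype_matrix`.
#' @param eqtl,mqtl,haqtl [map_cis_qtl()] results for mRNA, DNA methylation
#'   and H3K9ac (any may be NULL).
#' @param eqtm,eqth [map_eqtx()] results linking the gene's mRNA to DNAm
#'   sites and H3K9ac peaks (any may be NULL).
#' @param dnam,h3k9ac features x samples matrices for the mark layers.
#' @param factor_models list with optional entries `mrna`, `dnam`, `h3k9ac`,
#'   each a [estimate_hidden_factors()] model used for composite covariates.
#' @param phenotype_id phenotype identifier.
#' @param require `"both"` (default) or `"any"`; see Details.
#' @return an [lrn_node_set()].
#' @export
build_node_set <- function(gene, phenotype, expression, genotypes,
                           eqtl = NULL, mqtl = NULL, haqtl = NULL,
                           eqtm = NULL, eqth = NULL,
                           dnam = NULL, h3k9ac = NULL,
                           factor_models = list(),
                           phenotype_id = "phenotype",
                           require = c("both", "any")) {
  require <- match.arg(require)
  stopifnot(is.matrix(expression), gene %in% rownames(expression))
  dosage <- genotypes$dosage
  samples <- Reduce(intersect, list(colnames(expression), names(phenotype),
                                    colnames(dosage)))
  if (!is.null(dnam)) samples <- intersect(samples, colnames(dnam))
  if (!is.null(h3k9ac)) samples <- intersect(samples, colnames(h3k9ac))
  if (length(samples) < 10)
    stop("fewer than 10 shared samples", call. = FALSE)

  best_of <- function(tbl) if (is.null(tbl)) character(0) else best_snp_per_feature(tbl)
  e_snp <- best_of(eqtl)[gene]
  e_snp <- if (is.na(e_snp)) NULL else unname(e_snp)

  pick_marks <- function(eqtx, qtl_tbl) {
    if (is.null(eqtx) || is.null(qtl_tbl)) return(NULL)
    hits <- eqtx[eqtx$gene == gene & eqtx$significant, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    anchors <- best_of(qtl_tbl)
    hits <- hits[hits$peak %in% names(anchors), , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    hits$anchor <- unname(anchors[hits$peak])
    hits[order(hits$peak), , drop = FALSE]
  }
  m_marks <- pick_marks(eqtm, mqtl)
  h_marks <- pick_marks(eqth, haqtl)
  n_marks <- NROW(m_marks) + NROW(h_marks)

  eligible <- if (require == "both") !is.null(e_snp) && n_marks >= 1
              else !is.null(e_snp) || n_marks >= 1
  if (!eligible)
    stop(errorCondition(
      paste0("gene ", gene, " is ineligible for LRN construction (needs ",
             if (require == "both") "an eQTL SNP and >= 1 SNP-associated mark"
             else "an eQTL SNP or a SNP-associated mark", ")"),
      class = c("lrn_ineligible_gene", "error", "condition")))

  qn <- function(v) quantile_normalize(v)
  imputed_dosage <- function(snp) {
    v <- dosage[snp, samples]
    if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  }
  vals <- list(); classes <- character(0)
  anchors <- character(0); covt <- character(0)
  add <- function(name, class, v) {
    vals[[name]] <<- v
    classes[[name]] <<- class
  }
  add("p", "p", qn(phenotype[samples]))
  add("e", "e", qn(expression[gene, samples]))
  if (!is.null(e_snp)) {
    add("g_e", "g_e", imputed_dosage(e_snp))
    anchors[["g_e"]] <- "e"
  }
  add_marks <- function(marks, layer_mat, mcls) {
    if (is.null(marks)) return(invisible())
    gcls <- paste0("g_", mcls); ccls <- paste0("C_", mcls)
    fm <- factor_models[[if (mcls == "m") "dnam" else "h3k9ac"]]
    for (i in seq_len(nrow(marks))) {
      pk <- marks$peak[i]
      nd <- paste0(mcls, ":", pk)
      add(nd, mcls, qn(layer_mat[pk, samples]))
      gn <- paste0(gcls, ":", pk)
      add(gn, gcls, imputed_dosage(marks$anchor[i]))
      anchors[[gn]] <<- nd
      if (!is.null(fm) && fm$k > 0) {
        cn <- paste0(ccls, ":", pk)
        add(cn, ccls, qn(composite_covariate(fm, pk)[samples]))
        covt[[cn]] <<- nd
      }
    }
  }
  add_marks(m_marks, dnam, "m")
  add_marks(h_marks, h3k9ac, "h")
  fm_e <- factor_models[["mrna"]]
  if (!is.null(fm_e) && fm_e$k > 0) {
    add("C_e", "C_e", qn(composite_covariate(fm_e, gene)[samples]))
    covt[["C_e"]] <- "e"
  }
  values <- do.call(cbind, vals)
  rownames(values) <- samples
  lrn_node_set(values, classes = classes, anchors = anchors,
               cov_targets = covt, gene = gene, phenotype_id = phenotype_id)
}

#' Node set for one simulated gene
#'
#' Builds the [lrn_node_set()] of a gene directly from a simulated cascade
#' (bypassing association mapping): template nodes become network nodes,
#' anchor SNPs are taken from the template topology, non-genetic values are
#' quantile-normalized.
#'
#' @param sim an `lrn_sim` from [simulate_lrn_cascade()].
#' @param gene gene identifier (e.g. `"gene001"`).
#' @param phenotype optional replacement phenotype vector (one value per
#'   sample), e.g. one context from [simulate_phenotype_contexts()]; default
#'   is the gene's simulated phenotype.
#' @param phenotype_id phenotype identifier recorded in the node set.
#' @return an [lrn_node_set()].
#' @export
node_set_from_sim <- function(sim, gene, phenotype = NULL,
                              phenotype_id = "phenotype") {
  stopifnot(inherits(sim, "lrn_sim"))
  fm <- sim$feature_map[sim$feature_map$gene == gene, , drop = FALSE]
  if (nrow(fm) == 0) stop("unknown gene: ", gene, call. = FALSE)
  tg <- sim$true_dag
  nodes <- fm$node
  cls <- setNames(fm$class, nodes)
  vals <- list()
  for (i in seq_len(nrow(fm))) {
    nd <- fm$node[i]; cl <- fm$class[i]; ft <- fm$feature[i]
    v <- switch(cl,
      e = sim$omics$mrna[ft, ],
      m = sim$omics$dnam[ft, ],
      h = sim$omics$h3k9ac[ft, ],
      p = if (is.null(phenotype)) sim$phenotype_by_gene[gene, ] else phenotype,
      sim$genotypes$dosage[ft, ])  # SNP classes
    if (!is_snp_class(cl)) v <- quantile_normalize(v)
    vals[[nd]] <- v
  }
  anchors <- character(0)
  for (nd in nodes[is_snp_class(cls)]) {
    tgt <- igraph::neighbors(tg, nd, mode = "out")$name
    tgt <- intersect(tgt, nodes[cls %in% c("e", "m", "h")])
    if (length(tgt) == 0)
      stop("anchor SNP ", nd, " has no molecular target in the template",
           call. = FALSE)
    anchors[[nd]] <- tgt[[1]]
  }
  values <- do.call(cbind, vals)
  lrn_node_set(values, classes = cls, anchors = anchors, gene = gene,
               phenotype_id = phenotype_id)
}
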