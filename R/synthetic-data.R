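# Synthetic multi-omic cascades with known causal structure.
#
# Every node in a cascade template belongs to one of the LRN classes:
#   p (phenotype), e (mRNA), m (DNA methylation), h (H3K9ac),
#   g_e / g_m / g_h (anchor SNPs), C_* (composite covariates).
# Node class is inferred from the node name prefix, so templates can use
# names like "m1", "m2", "g_m1" for multi-mark cascades.

#' Infer the LRN node class from node names
#'
#' @param x character vector of node names (e.g. `"g_m1"`, `"m2"`, `"e"`).
#' @return character vector of classes in
#'   `{"p","e","m","h","g_e","g_m","g_h","C_e","C_m","C_h"}`.
#' @examples
#' node_class(c("p", "e", "m1", "g_m1", "C_e"))
#' @export
node_class <- function(x) {
  cls <- character(length(x))
  for (i in seq_along(x)) {
    nm <- x[[i]]
    cls[[i]] <-
      if (nm == "p" || startsWith(nm, "p_")) "p"
      else if (startsWith(nm, "g_e")) "g_e"
      else if (startsWith(nm, "g_m")) "g_m"
      else if (startsWith(nm, "g_h")) "g_h"
      else if (startsWith(nm, "C_e")) "C_e"
      else if (startsWith(nm, "C_m")) "C_m"
      else if (startsWith(nm, "C_h")) "C_h"
      else if (startsWith(nm, "e")) "e"
      else if (startsWith(nm, "m")) "m"
      else if (startsWith(nm, "h")) "h"
      else stop("cannot infer node class from name: ", nm, call. = FALSE)
  }
  cls
}

is_snp_class <- function(cls) cls %in% c("g_e", "g_m", "g_h")
is_covariate_class <- function(cls) cls %in% c("C_e", "C_m", "C_h")

#' Default cascade template: anchored methylation-to-phenotype chain
#'
#' The chain `g_m -> m -> e -> p`: a SNP controls a DNA-methylation site,
#' which controls mRNA, which controls the phenotype.
#'
#' @return data.frame with columns `parent`, `child`.
#' @export
default_template <- function() {
  data.frame(parent = c("g_m", "m", "e"),
             child  = c("m", "e", "p"),
             stringsAsFactors = FALSE)
}

template_graph <- function(template) {
  nodes <- unique(c(template$parent, template$child))
  igraph::graph_from_data_frame(template, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Configuration for a synthetic LRN cascade
#'
#' Defines the generative conditions for [simulate_lrn_cascade()]: a causal
#' DAG template over typed nodes, standardized edge effects, Gaussian noise,
#' genotype allele-frequency range and shared hidden confounding.
#'
#' @param n_samples number of samples (individuals).
#' @param n_genes number of independent replicate genes to simulate.
#' @param template edge-list data.frame (`parent`, `child`) over node names;
#'   must be acyclic and SNP-class nodes must have no incoming edges.
#' @param effect_sizes standardized regression coefficient per edge: a single
#'   number applied to every edge, or a vector named `"parent->child"`.
#' @param noise_sd standard deviation of the Gaussian noise added to every
#'   non-root node.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param n_hidden_factors number of shared hidden factors loading on all
#'   molecular-layer nodes (e, m, h), emulating residual batch /
#'   cell-composition confounding.
#' @param factor_strength standardized loading of each hidden factor on each
#'   molecular node.
#' @param n_decoy_snps number of additional effect-free SNPs placed inside
#'   each molecular feature's cis window (candidates for QTL mapping).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return an object of class `cascade_config`.
#' @examples
#' cfg <- cascade_config(n_samples = 100, seed = 7)
#' @export
cascade_config <- function(n_samples = 400,
                           n_genes = 1,
                           template = default_template(),
                           effect_sizes = 0.7,
                           noise_sd = 0.5,
                           maf_range = c(0.05, 0.5),
                           n_hidden_factors = 1,
                           factor_strength = 0.2,
                           n_decoy_snps = 3,
                           seed = 1L) {
  stopifnot(is.data.frame(template), all(c("parent", "child") %in% names(template)))
  if (n_samples < 2 || n_genes < 1)
    stop("n_samples must be >= 2 and n_genes >= 1", call. = FALSE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  if (n_hidden_factors < 0 || n_decoy_snps < 0)
    stop("counts must be non-negative", call. = FALSE)
  g <- template_graph(template)
  if (!igraph::is_dag(g))
    stop("true_dag template must be acyclic", call. = FALSE)
  cls <- node_class(igraph::V(g)$name)
  indeg <- igraph::degree(g, mode = "in")
  if (any(is_snp_class(cls) & indeg > 0))
    stop("SNP-class nodes must have no incoming template edges", call. = FALSE)
  if (any(is_covariate_class(cls)))
    stop("covariate nodes are derived, not template nodes", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 template = template,
                 effect_sizes = effect_sizes,
                 noise_sd = noise_sd,
                 maf_range = maf_range,
                 n_hidden_factors = as.integer(n_hidden_factors),
                 factor_strength = factor_strength,
                 n_decoy_snps = as.integer(n_decoy_snps),
                 seed = as.integer(seed)),
            class = "cascade_config")
}

edge_effect <- function(config, parent, child) {
  es <- config$effect_sizes
  if (is.null(names(es))) return(as.numeric(es[[1]]))
  key <- paste0(parent, "->", child)
  if (key %in% names(es)) return(as.numeric(es[[key]]))
  if (".default" %in% names(es)) return(as.numeric(es[[".default"]]))
  stop("no effect size given for edge ", key, call. = FALSE)
}

#' Simulate biallelic SNP dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor allele frequency uniformly from `maf_range` and
#' dosages from Binomial(2, MAF) per sample, so all simulated MAFs satisfy
#' the lower bound by construction.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range frequency pair within (0, 0.5].
#' @param seed optional integer seed.
#' @param chrom chromosome label for all SNPs.
#' @param positions optional integer base-pair positions (defaults to an
#'   evenly spaced grid).
#' @return a `genotype_matrix`: list with `dosage` (SNPs x samples matrix of
#'   values 0/1/2) and `info` (data.frame: snp, chrom, pos, maf, maf_emp).
#' @examples
#' g <- simulate_genotypes(50, 4, seed = 1)
#' range(g$info$maf)
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               seed = NULL, chrom = "1", positions = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2 || !is.numeric(n_snps) || n_snps < 1)
    stop("n_samples must be >= 2 and n_snps >= 1", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(n_samples); n_snps <- as.integer(n_snps)
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n_snps * n_samples, 2L, rep(maf, n_samples)),
                   nrow = n_snps, ncol = n_samples)
  rownames(dosage) <- sprintf("snp%04d", seq_len(n_snps))
  colnames(dosage) <- sprintf("S%04d", seq_len(n_samples))
  if (is.null(positions)) positions <- seq_len(n_snps) * 1000L
  structure(list(dosage = dosage,
                 info = data.frame(snp = rownames(dosage),
                                   chrom = chrom,
                                   pos = as.integer(positions),
                                   maf = maf,
                                   maf_emp = rowMeans(dosage) / 2,
                                   stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

## Genomic layout of one simulated gene: features are spaced so that the
## standard cis windows (5 kb mQTL, 50 kb eQTL/haQTL, 1 Mb eQTM/eQTH) behave
## as in real annotation. Genes sit 3 Mb apart so windows never overlap.
.gene_base <- function(i) 1000000L + (i - 1L) * 3000000L

#' Simulate a multi-omic dataset from a known causal cascade
#'
#' Generates `n_genes` independent replicates of the configured causal DAG.
#' Every non-root node equals the effect-weighted sum of its standardized
#' parents, plus hidden-factor loadings (molecular nodes only) and Gaussian
#' noise, evaluated in topological order. SNP nodes are Hardy-Weinberg
#' dosages; DNA methylation is generated on a latent Gaussian (M-like) scale
#' and also exported on the Beta scale via the inverse-logistic transform.
#'
#' @param config a [cascade_config()].
#' @return an object of class `lrn_sim`: list with elements `genotypes`
#'   (a `genotype_matrix` covering anchor and decoy SNPs), `omics` (list of
#'   features x samples matrices: `mrna`, `dnam`, `dnam_beta`, `h3k9ac`),
#'   `annotations` (per-layer data.frames: feature, chrom, pos, strand),
#'   `phenotype` (named numeric vector), `true_dag` (igraph of the template),
#'   `true_relations` (data.frame from [true_relations()]), `feature_map`
#'   (gene x template-node to feature-id table), `hidden_factors`
#'   (factors x samples matrix) and `config`.
#' @examples
#' sim <- simulate_lrn_cascade(cascade_config(n_samples = 60, seed = 2))
#' names(sim$omics)
#' @export
simulate_lrn_cascade <- function(config) {
  stopifnot(inherits(config, "cascade_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  tg <- template_graph(config$template)
  nodes <- igraph::V(tg)$name
  cls <- setNames(node_class(nodes), nodes)
  if (sum(cls == "e") != 1)
    stop("template must contain exactly one mRNA (e) node", call. = FALSE)
  topo <- igraph::topo_sort(tg, mode = "out")$name
  snp_nodes <- nodes[is_snp_class(cls)]
  mol_classes <- c("e", "m", "h")

  Fm <- if (config$n_hidden_factors > 0) {
    matrix(rnorm(config$n_hidden_factors * n), nrow = config$n_hidden_factors,
           dimnames = list(sprintf("F%d", seq_len(config$n_hidden_factors)), samples))
  } else {
    matrix(0, nrow = 0, ncol = n, dimnames = list(NULL, samples))
  }
  factor_term <- if (nrow(Fm) > 0) config$factor_strength * colSums(Fm) else rep(0, n)

  std <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }

  geno_rows <- list(); geno_info <- list()
  mrna <- NULL; dnam <- list(); h3k9ac <- list()
  annot_m <- list(); annot_h <- list(); annot_e <- list()
  fmap <- list()
  pheno_mat <- NULL  # collects the single p node per gene

  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", gi)
    base <- .gene_base(gi)
    vals <- list()
    # per-node genomic anchor positions
    mpos <- hpos <- integer(0)
    mi <- hi <- 0L
    pos_of <- setNames(vector("list", length(nodes)), nodes)
    for (nd in nodes) {
      if (cls[[nd]] == "e") pos_of[[nd]] <- base
      else if (cls[[nd]] == "m") { mi <- mi + 1L; pos_of[[nd]] <- base + 20000L * mi }
      else if (cls[[nd]] == "h") { hi <- hi + 1L; pos_of[[nd]] <- base + 50000L * hi }
    }
    for (nd in nodes) {
      if (cls[[nd]] == "g_e") pos_of[[nd]] <- base + 10000L
      else if (cls[[nd]] == "g_m") {
        tgt <- igraph::neighbors(tg, nd, mode = "out")$name
        tgt <- tgt[cls[tgt] == "m"][1]
        pos_of[[nd]] <- (if (!is.na(tgt)) pos_of[[tgt]] else base) + 1000L
      } else if (cls[[nd]] == "g_h") {
        tgt <- igraph::neighbors(tg, nd, mode = "out")$name
        tgt <- tgt[cls[tgt] == "h"][1]
        pos_of[[nd]] <- (if (!is.na(tgt)) pos_of[[tgt]] else base) + 10000L
      }
    }

    for (nd in topo) {
      if (is_snp_class(cls[[nd]])) {
        maf <- runif(1, config$maf_range[1], config$maf_range[2])
        dos <- rbinom(n, 2L, maf)
        sid <- paste0(gid, ".", nd)
        geno_rows[[sid]] <- dos
        geno_info[[sid]] <- data.frame(snp = sid, chrom = "1",
                                       pos = pos_of[[nd]], maf = maf,
                                       maf_emp = mean(dos) / 2,
                                       stringsAsFactors = FALSE)
        vals[[nd]] <- dos
      } else {
        parents <- igraph::neighbors(tg, nd, mode = "in")$name
        v <- rnorm(n, 0, config$noise_sd)
        for (pa in parents)
          v <- v + edge_effect(config, pa, nd) * std(vals[[pa]])
        if (cls[[nd]] %in% mol_classes) v <- v + factor_term
        vals[[nd]] <- v
      }
      fmap[[length(fmap) + 1L]] <- data.frame(
        gene = gid, node = nd, class = cls[[nd]],
        feature = if (cls[[nd]] == "e") gid
                  else if (cls[[nd]] == "p") paste0(gid, ".p")
                  else paste0(gid, ".", nd),
        stringsAsFactors = FALSE)
    }

    # decoy SNPs inside each molecular feature's cis window
    for (nd in nodes[cls[nodes] %in% mol_classes]) {
      w_step <- switch(cls[[nd]], e = 7000L, m = 1200L, h = 7000L)
      for (k in seq_len(config$n_decoy_snps)) {
        maf <- runif(1, config$maf_range[1], config$maf_range[2])
        dos <- rbinom(n, 2L, maf)
        sid <- sprintf("%s.null.%s.%d", gid, nd, k)
        geno_rows[[sid]] <- dos
        geno_info[[sid]] <- data.frame(snp = sid, chrom = "1",
                                       pos = pos_of[[nd]] + k * w_step,
                                       maf = maf, maf_emp = mean(dos) / 2,
                                       stringsAsFactors = FALSE)
      }
    }

    e_node <- nodes[cls == "e"]
    mrna <- rbind(mrna, matrix(vals[[e_node]], nrow = 1))
    rownames(mrna)[nrow(mrna)] <- gid
    annot_e[[gid]] <- data.frame(feature = gid, chrom = "1", pos = base,
                                 strand = "+", stringsAsFactors = FALSE)
    for (nd in nodes[cls == "m"]) {
      fid <- paste0(gid, ".", nd)
      dnam[[fid]] <- vals[[nd]]
      annot_m[[fid]] <- data.frame(feature = fid, chrom = "1",
                                   pos = pos_of[[nd]], strand = "*",
                                   stringsAsFactors = FALSE)
    }
    for (nd in nodes[cls == "h"]) {
      fid <- paste0(gid, ".", nd)
      h3k9ac[[fid]] <- vals[[nd]]
      annot_h[[fid]] <- data.frame(feature = fid, chrom = "1",
                                   pos = pos_of[[nd]], strand = "*",
                                   stringsAsFactors = FALSE)
    }
    if (any(cls == "p")) {
      p_node <- nodes[cls == "p"][1]
      pheno_mat <- rbind(pheno_mat, vals[[p_node]])
      rownames(pheno_mat)[nrow(pheno_mat)] <- gid
    }
  }

  list_to_matrix <- function(l) {
    if (length(l) == 0)
      return(matrix(numeric(0), nrow = 0, ncol = n, dimnames = list(NULL, samples)))
    m <- do.call(rbind, l)
    dimnames(m) <- list(names(l), samples)
    m
  }
  dosage <- list_to_matrix(geno_rows)
  genotypes <- structure(list(dosage = dosage,
                              info = do.call(rbind, c(geno_info, list(make.row.names = FALSE)))),
                         class = "genotype_matrix")
  dnam_m <- list_to_matrix(dnam)
  omics <- list(mrna = `dimnames<-`(mrna, list(rownames(mrna), samples)),
                dnam = dnam_m,
                dnam_beta = plogis(dnam_m),
                h3k9ac = list_to_matrix(h3k9ac))
  if (!is.null(pheno_mat)) colnames(pheno_mat) <- samples
  phenotype <- if (is.null(pheno_mat)) NULL else setNames(pheno_mat[1, ], samples)

  sim <- structure(list(genotypes = genotypes,
                        omics = omics,
                        annotations = list(
                          mrna = do.call(rbind, c(annot_e, list(make.row.names = FALSE))),
                          dnam = if (length(annot_m)) do.call(rbind, c(annot_m, list(make.row.names = FALSE))) else NULL,
                          h3k9ac = if (length(annot_h)) do.call(rbind, c(annot_h, list(make.row.names = FALSE))) else NULL),
                        phenotype = phenotype,
                        phenotype_by_gene = pheno_mat,
                        true_dag = tg,
                        feature_map = do.call(rbind, c(fmap, list(make.row.names = FALSE))),
                        hidden_factors = Fm,
                        config = config),
                   class = "lrn_sim")
  sim$true_relations <- true_relations(sim)
  sim
}

#' Ground-truth relation labels from a causal DAG
#'
#' Labels every ordered node pair by directed-path reachability: `upstream`
#' if a path source -> reference exists, `downstream` if reference -> source,
#' `independent` otherwise. Applied to a simulated dataset it returns the
#' labels implied by the generating template.
#'
#' @param x an `lrn_sim` object or an igraph DAG.
#' @return data.frame with columns `source`, `reference`, `label`.
#' @examples
#' sim <- simulate_lrn_cascade(cascade_config(n_samples = 50, seed = 3))
#' true_relations(sim)
#' @export
true_relations <- function(x) {
  dag <- if (inherits(x, "lrn_sim")) x$true_dag else x
  stopifnot(igraph::is_igraph(dag))
  if (!igraph::is_dag(dag)) stop("graph must be acyclic", call. = FALSE)
  nodes <- igraph::V(dag)$name
  d <- igraph::distances(dag, mode = "out")
  out <- expand.grid(source = nodes, reference = nodes,
                     stringsAsFactors = FALSE)
  out <- out[out$source != out$reference, , drop = FALSE]
  out$label <- mapply(function(a, b) {
    if (is.finite(d[a, b])) "upstream"
    else if (is.finite(d[b, a])) "downstream"
    else "independent"
  }, out$source, out$reference)
  rownames(out) <- NULL
  out
}

#' Regenerate phenotype contexts for a simulated cascade
#'
#' Produces additional phenotype realizations for every gene by re-running
#' the template's phenotype equation (same parents, effects and noise level,
#' fresh noise). This emulates building LRNs for several phenotypes that
#' share the molecular data.
#'
#' @param sim an `lrn_sim` whose template contains a phenotype node.
#' @param n_contexts number of phenotype contexts to generate.
#' @param seed optional integer seed.
#' @return list of length `n_contexts`; each element a genes x samples
#'   matrix of phenotype values.
#' @export
simulate_phenotype_contexts <- function(sim, n_contexts = 4, seed = NULL) {
  stopifnot(inherits(sim, "lrn_sim"), n_contexts >= 1)
  if (!is.null(seed)) set.seed(seed)
  tg <- sim$true_dag
  cls <- setNames(node_class(igraph::V(tg)$name), igraph::V(tg)$name)
  p_node <- names(cls)[cls == "p"]
  if (length(p_node) != 1)
    stop("template has no phenotype node", call. = FALSE)
  parents <- igraph::neighbors(tg, p_node, mode = "in")$name
  config <- sim$config
  n <- config$n_samples
  genes <- rownames(sim$omics$mrna)
  std <- function(v) { s <- sd(v); if (s == 0) rep(0, length(v)) else (v - mean(v)) / s }
  fm <- sim$feature_map
  lapply(seq_len(n_contexts), function(ctx) {
    out <- matrix(rnorm(length(genes) * n, 0, config$noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes, colnames(sim$omics$mrna)))
    for (gi in seq_along(genes)) {
      for (pa in parents) {
        ft <- fm$feature[fm$gene == genes[gi] & fm$node == pa]
        pcls <- cls[[pa]]
        v <- switch(pcls,
          e = sim$omics$mrna[ft, ],
          m = sim$omics$dnam[ft, ],
          h = sim$omics$h3k9ac[ft, ],
          sim$genotypes$dosage[ft, ])
        out[gi, ] <- out[gi, ] + edge_effect(config, pa, p_node) * std(v)
      }
    }
    out
  })
}
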