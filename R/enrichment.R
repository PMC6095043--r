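# Enrichment statistics: genomic-annotation assignment with Fisher tests,
# hypergeometric gene-set enrichment with the dual significance rule, and
# permutation nulls for per-label aggregate statistics.

#' Assign genomic positions to annotation categories
#'
#' A position (a peak or DNAm-site center) is assigned to the first matching
#' category with precedence promoter > gene body > downstream > intergenic,
#' across all gene models. Promoter = TSS +/- 3 kb (symmetric on either
#' strand); downstream = the 3 kb past the transcriptional end site (TED),
#' strand-oriented; gene body = the non-promoter TSS-TED span.
#'
#' @param chrom character vector of chromosomes (recycled).
#' @param position integer vector of positions (1-based).
#' @param gene_models data.frame with columns `gene`, `chrom`, `tss`, `ted`,
#'   `strand` (`"+"` or `"-"`; minus-strand genes have `tss > ted`).
#' @param flank promoter/downstream flank size (default 3000 bp).
#' @return character vector in
#'   `{"promoter", "gene_body", "downstream", "intergenic"}`.
#' @examples
#' gm <- data.frame(gene = "g1", chrom = "1", tss = 10000, ted = 20000,
#'                  strand = "+")
#' annotate_position("1", c(10000, 15000, 22000, 30000), gm)
#' @export
annotate_position <- function(chrom, position, gene_models, flank = 3000) {
  stopifnot(all(c("gene", "chrom", "tss", "ted", "strand") %in% names(gene_models)))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  if (any(position < 1)) stop("positions must be >= 1", call. = FALSE)
  in_prom <- in_body <- in_down <- rep(FALSE, n)
  for (g in seq_len(nrow(gene_models))) {
    gm <- gene_models[g, ]
    on_chr <- chrom == gm$chrom
    prom <- on_chr & position >= gm$tss - flank & position <= gm$tss + flank
    body <- on_chr & position >= min(gm$tss, gm$ted) &
      position <= max(gm$tss, gm$ted)
    down <- if (gm$strand == "-") {
      on_chr & position >= gm$ted - flank & position <= gm$ted
    } else {
      on_chr & position >= gm$ted & position <= gm$ted + flank
    }
    in_prom <- in_prom | prom
    in_body <- in_body | body
    in_down <- in_down | down
  }
  out <- rep("intergenic", n)
  out[in_down] <- "downstream"
  out[in_body] <- "gene_body"
  out[in_prom] <- "promoter"
  out
}

#' Fisher's exact test for category enrichment
#'
#' Builds the 2x2 table (hits in category, hits elsewhere; non-hits in
#' category, non-hits elsewhere) over a finite universe and tests it with
#' Fisher's exact test. The reported odds ratio is the sample (unconditional)
#' odds ratio.
#'
#' @param hits_in_category number of hit features inside the category.
#' @param hits_total total number of hit features.
#' @param category_total number of features in the category.
#' @param universe universe size.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return data.frame: counts, `odds_ratio`, `p_value`.
#' @examples
#' fisher_enrichment(10, 10, 10, 20)
#' @export
fisher_enrichment <- function(hits_in_category, hits_total, category_total,
                              universe, alternative = "two.sided") {
  a <- hits_in_category
  b <- hits_total - a
  c_ <- category_total - a
  d <- universe - hits_total - c_
  if (any(c(a, b, c_, d) < 0))
    stop("inconsistent 2x2 margins", call. = FALSE)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = alternative)
  or <- (a * d) / (b * c_)  # sample odds ratio; Inf/NaN at degenerate margins
  data.frame(hits_in_category = a, hits_out = b,
             misses_in_category = c_, misses_out = d,
             odds_ratio = or, p_value = ft$p.value)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query set and
#' each term set, within a background universe (terms are intersected with
#' the background before testing; the query must be a subset of the
#' background). Benjamini-Hochberg q-values are computed across terms and
#' the dual criterion (q < 0.05 and overlap > 2) sets the `significant`
#' flag.
#'
#' @param query character vector of query identifiers.
#' @param terms named list of term sets (character vectors).
#' @param background character vector: the background universe.
#' @param q_cutoff,min_overlap the dual significance rule (defaults 0.05
#'   and overlap strictly greater than 2).
#' @return data.frame: `term`, `overlap`, `term_size`, `query_size`,
#'   `background_size`, `odds_ratio`, `p_value`, `qvalue`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, terms, background,
                                      q_cutoff = 0.05, min_overlap = 2) {
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background", call. = FALSE)
  if (length(query) == 0 || length(terms) == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), query_size = integer(0),
                      background_size = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), qvalue = numeric(0),
                      significant = logical(0)))
  N <- length(background); n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    ts <- intersect(unique(terms[[tm]]), background)
    K <- length(ts)
    k <- length(intersect(query, ts))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(term = tm, overlap = k, term_size = K, query_size = n,
               background_size = N, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- bh_fdr(out$p_value)
  out$significant <- out$qvalue < q_cutoff & out$overlap > min_overlap
  out
}

#' Permutation null for a per-label aggregate statistic
#'
#' Tests whether the aggregate (by default the median) of a per-feature
#' statistic within a focal label class differs from what label shuffling
#' would produce: labels are permuted across features `n_perm` times and
#' the empirical p-value uses the `(1 + count) / (n_perm + 1)` convention,
#' per tail.
#'
#' @param labels character vector of relation labels, one per feature.
#' @param statistic numeric per-feature statistic (e.g. TF-binding-site
#'   count, or count per 100 bp of peak width).
#' @param focal_label the label class whose aggregate is tested.
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`
#'   (twice the smaller tail, capped at 1).
#' @param aggregate aggregation function (default [median()]).
#' @return list with `observed`, `null` (numeric vector of permuted
#'   aggregates), `p_value`, `n_perm`.
#' @export
permutation_label_null <- function(labels, statistic, focal_label,
                                   n_perm = 10000, seed = NULL,
                                   alternative = c("greater", "less", "two.sided"),
                                   aggregate = median) {
  alternative <- match.arg(alternative)
  stopifnot(length(labels) == length(statistic))
  if (!focal_label %in% labels)
    stop("focal_label not present in labels", call. = FALSE)
  if (any(!is.finite(statistic)))
    stop("statistic must be defined (finite) for every feature", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- sum(labels == focal_label)
  observed <- aggregate(statistic[labels == focal_label])
  null <- vapply(seq_len(n_perm), function(b)
    aggregate(statistic[sample.int(length(statistic), k)]), numeric(1))
  p_g <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_l <- (1 + sum(null <= observed)) / (n_perm + 1)
  p <- switch(alternative, greater = p_g, less = p_l,
              two.sided = min(1, 2 * min(p_g, p_l)))
  list(observed = observed, null = null, p_value = p, n_perm = n_perm)
}
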