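test_that("cis windows are symmetric, truncated and validated", {
  w <- define_cis_window("1", 100000, 50000, "geneA")
  expect_equal(c(w$start, w$end), c(50000, 150000))
  w2 <- define_cis_window("2", 3000, 5000)
  expect_equal(c(w2$start, w2$end), c(1, 8000))  # left-truncated
  w3 <- define_cis_window("1", 2e6, 1e6)
  expect_equal(c(w3$start, w3$end), c(1e6, 3e6))
  expect_error(define_cis_window("1", 100, 0), "w must be")
})

test_that("marginal association matches the lm() oracle to 1e-10", {
  set.seed(1)
  for (rep in 1:5) {
    y <- rnorm(100); x <- rnorm(100)
    got <- marginal_association(y, x)
    fit <- summary(lm(y ~ x))$coefficients["x", ]
    expect_equal(got$beta, unname(fit["Estimate"]), tolerance = 1e-10)
    expect_equal(got$se, unname(fit["Std. Error"]), tolerance = 1e-10)
    expect_equal(got$p_value, unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
  }
  perfect <- marginal_association(1:10, (1:10) * 2)
  expect_equal(perfect$beta, 0.5)
  expect_equal(perfect$p_value, 0)
  # orthogonal constructed vectors give slope 0
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  expect_equal(marginal_association(y, x)$beta, 0)
  expect_error(marginal_association(rnorm(10), rep(1, 10)), "constant")
})

test_that("permutation p-values hit the floor for perfect association", {
  set.seed(2)
  X <- matrix(rnorm(5 * 60), nrow = 5)
  y <- X[1, ]
  pm <- permutation_min_p(y, X, n_perm = 500, seed = 3)
  expect_equal(pm$p_empirical, 1 / 501)
  expect_equal(pm$best, 1)
  expect_error(permutation_min_p(y, X, n_perm = 50), "n_perm")
})

test_that("single-candidate empirical p agrees with the statistic's null rank", {
  set.seed(4)
  n <- 80
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  pm <- permutation_min_p(y, x, n_perm = 1000, seed = 5)
  # brute-force oracle: same permutations, rank of |cor|
  set.seed(5)
  ys <- scale(y)[, 1]; xs <- scale(x)[, 1]
  r_obs <- abs(sum(xs * ys) / (n - 1))
  null <- replicate(1000, abs(sum(xs * ys[sample.int(n)]) / (n - 1)))
  expect_equal(pm$p_empirical, (1 + sum(null >= r_obs)) / 1001)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  set.seed(6)
  ps <- replicate(120, {
    y <- rnorm(40); X <- matrix(rnorm(3 * 40), nrow = 3)
    permutation_min_p(y, X, n_perm = 120)$p_empirical
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH q-values match the hand example and a step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  # independent textbook step-up implementation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(7)
  p <- runif(1000)
  expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey's pi1 estimates alternative fractions", {
  set.seed(8)
  null <- runif(10000)
  expect_lt(abs(storey_pi1(null)$pi1), 0.05)
  mix <- c(runif(3000, 0, 1e-3), runif(7000))
  pi1 <- storey_pi1(mix)$pi1
  expect_gt(pi1, 0.25); expect_lt(pi1, 0.35)
  expect_equal(storey_pi1(rep(1e-7, 500))$pi1, 1)  # saturated alternative
})

test_that("cis-QTL mapping respects windows and recovers planted signals", {
  tpl <- data.frame(parent = "g_e", child = "e")
  sim <- simulate_lrn_cascade(cascade_config(
    n_samples = 150, n_genes = 12, template = tpl, effect_sizes = 0.8,
    n_hidden_factors = 0, seed = 9))
  qtl <- map_cis_qtl(sim$omics$mrna, sim$genotypes, sim$annotations$mrna,
                     w = 50000, n_perm = 200, seed = 10)
  expect_true(all(qtl$n_tested == 4))  # anchor + 3 decoys per gene
  expect_gt(mean(qtl$significant), 0.8)
  # the anchor SNP wins over the decoys for nearly all genes
  expect_gt(mean(grepl("g_e$", qtl$variant)), 0.8)
  # permutation p respects its floor
  expect_true(all(qtl$perm_p >= 1 / 201))
  # an 8 kb window excludes the anchor SNP placed 10 kb from the TSS
  qtl5 <- map_cis_qtl(sim$omics$mrna, sim$genotypes, sim$annotations$mrna,
                      w = 8000, n_perm = 200, seed = 10)
  expect_false(any(grepl("g_e$", qtl5$variant)))
  expect_true(all(qtl5$n_tested == 1))  # only the 7 kb decoy remains
})

test_that("features without candidate SNPs are reported, not dropped", {
  sim <- simulate_lrn_cascade(cascade_config(
    n_samples = 60, n_genes = 2, template = data.frame(parent = "g_e", child = "e"),
    n_hidden_factors = 0, seed = 11))
  annot <- sim$annotations$mrna
  annot$pos[2] <- annot$pos[2] + 2e6  # move the anchor away from its SNPs
  qtl <- map_cis_qtl(sim$omics$mrna, sim$genotypes, annot,
                     w = 5000, n_perm = 100, seed = 12, min_samples = 30)
  expect_equal(nrow(qtl), 2)
  expect_equal(qtl$n_tested[2], 0L)
  expect_true(is.na(qtl$variant[2]))
})

test_that("exact best-SNP ties break to the lowest genomic position", {
  set.seed(13)
  n <- 60
  dos <- rbinom(n, 2, 0.4)
  geno <- list(dosage = rbind(snpB = dos, snpA = dos),
               info = data.frame(snp = c("snpB", "snpA"), chrom = "1",
                                 pos = c(200L, 100L)))
  colnames(geno$dosage) <- sprintf("S%03d", 1:n)
  y <- matrix(0.9 * dos + rnorm(n, 0, 0.3), nrow = 1,
              dimnames = list("feat", colnames(geno$dosage)))
  qtl <- map_cis_qtl(y, geno, data.frame(feature = "feat", chrom = "1", pos = 150),
                     w = 1000, n_perm = 100, seed = 14)
  expect_identical(qtl$variant, "snpA")  # identical dosages; lower pos wins
  expect_identical(best_snp_per_feature(qtl), c(feat = "snpA"))
})

test_that("eQTM mapping keeps signs, applies dual FDR and honors the 1 Mb window", {
  tpl <- data.frame(parent = c("g_m", "m"), child = c("m", "e"))
  sim <- simulate_lrn_cascade(cascade_config(
    n_samples = 200, n_genes = 10, template = tpl,
    effect_sizes = c("g_m->m" = 0.7, "m->e" = -0.7),  # suppressor marks
    n_hidden_factors = 0, seed = 15))
  eqtm <- map_eqtx(sim$omics$mrna, sim$omics$dnam, sim$annotations$mrna,
                   sim$annotations$dnam, w = 1e6, n_perm = 200, seed = 16)
  hits <- eqtm[eqtm$significant, ]
  expect_gt(nrow(hits), 5)
  expect_true(all(hits$r < 0))  # simulated negative effect keeps its sign
  expect_true(all(hits$q_pair <= 0.05 & hits$q_gene <= 0.05))
  # peaks 1.2 Mb away are never tested
  far <- sim$annotations$dnam
  far$pos <- far$pos + 1.2e6
  eqtm_far <- map_eqtx(sim$omics$mrna, sim$omics$dnam, sim$annotations$mrna,
                       far, w = 1e6, n_perm = 200, seed = 17)
  tested_own <- mapply(function(g, p) startsWith(p, g), eqtm_far$gene, eqtm_far$peak)
  expect_false(any(tested_own))
})

test_that("eQTM mapping stays null-calibrated on permuted expression", {
  tpl <- data.frame(parent = c("g_m", "m"), child = c("m", "e"))
  sim <- simulate_lrn_cascade(cascade_config(
    n_samples = 150, n_genes = 15, template = tpl, effect_sizes = 0,
    n_hidden_factors = 0, seed = 18))
  eqtm <- map_eqtx(sim$omics$mrna, sim$omics$dnam, sim$annotations$mrna,
                   sim$annotations$dnam, w = 1e6, n_perm = 200, seed = 19)
  expect_lte(sum(eqtm$significant), 1)
})

test_that("discoveries are invariant to sample ordering", {
  tpl <- data.frame(parent = "g_e", child = "e")
  sim <- simulate_lrn_cascade(cascade_config(
    n_samples = 80, n_genes = 4, template = tpl, n_hidden_factors = 0, seed = 20))
  qtl1 <- map_cis_qtl(sim$omics$mrna, sim$genotypes, sim$annotations$mrna,
                      w = 50000, n_perm = 100, seed = 21)
  perm <- sample(colnames(sim$omics$mrna))
  sim2 <- sim
  sim2$omics$mrna <- sim$omics$mrna[, perm, drop = FALSE]
  sim2$genotypes$dosage <- sim$genotypes$dosage[, perm, drop = FALSE]
  qtl2 <- map_cis_qtl(sim2$omics$mrna, sim2$genotypes, sim$annotations$mrna,
                      w = 50000, n_perm = 100, seed = 21)
  expect_identical(qtl1$variant, qtl2$variant)
  expect_equal(qtl1$nominal_p, qtl2$nominal_p, tolerance = 1e-10)
})
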