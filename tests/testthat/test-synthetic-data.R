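test_that("simulated genotypes respect MAF bounds and Hardy-Weinberg means", {
  g <- simulate_genotypes(200, 50, maf_range = c(0.05, 0.5), seed = 1)
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(g$info$maf >= 0.05 & g$info$maf <= 0.5))
  # at MAF fixed to 0.5 the expected dosage is 2 * 0.5 = 1
  g2 <- simulate_genotypes(20000, 5, maf_range = c(0.5, 0.5), seed = 2)
  expect_equal(unname(rowMeans(g2$dosage)), rep(1, 5), tolerance = 0.03)
  expect_error(simulate_genotypes(0, 5), "n_samples")
  expect_error(simulate_genotypes(50, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("genotype simulation is deterministic under a fixed seed", {
  a <- simulate_genotypes(100, 10, seed = 42)
  b <- simulate_genotypes(100, 10, seed = 42)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$info, b$info)
})

test_that("cascade config validates its invariants", {
  expect_error(cascade_config(noise_sd = 0), "noise_sd")
  expect_error(cascade_config(maf_range = c(0.05, 0.7)), "maf_range")
  cyc <- data.frame(parent = c("m", "e"), child = c("e", "m"))
  expect_error(cascade_config(template = cyc), "acyclic")
  snp_in <- data.frame(parent = c("e"), child = c("g_m"))
  expect_error(cascade_config(template = snp_in), "SNP")
})

test_that("cascade correlations match the linear-Gaussian recursion", {
  # analytic chain correlation without confounding:
  # corr(m, e) = b / sqrt(b^2 + sd^2) for standardized parent
  cfg <- cascade_config(n_samples = 4000, effect_sizes = 0.7, noise_sd = 0.5,
                        n_hidden_factors = 0, seed = 5)
  sim <- simulate_lrn_cascade(cfg)
  r_expect <- 0.7 / sqrt(0.7^2 + 0.5^2)
  r_obs <- cor(sim$omics$dnam[1, ], sim$omics$mrna[1, ])
  expect_equal(r_obs, r_expect, tolerance = 0.05)
  expect_lt(cor.test(sim$omics$dnam[1, ], sim$omics$mrna[1, ])$p.value, 1e-10)
})

test_that("zero effects give uncorrelated nodes; shared factors correlate layers", {
  cfg0 <- cascade_config(n_samples = 2000, effect_sizes = 0,
                         n_hidden_factors = 0, seed = 6,
                         template = data.frame(parent = c("g_m", "m", "e"),
                                               child = c("m", "e", "p")))
  sim0 <- simulate_lrn_cascade(cfg0)
  expect_lt(abs(cor(sim0$omics$dnam[1, ], sim0$omics$mrna[1, ])), 0.08)
  expect_lt(abs(cor(sim0$omics$mrna[1, ], sim0$phenotype)), 0.08)
  # hidden factor without a template edge between e and h still couples them
  tpl <- data.frame(parent = c("g_e", "g_h"), child = c("e", "h"))
  cfg1 <- cascade_config(n_samples = 2000, template = tpl, effect_sizes = 0.5,
                         n_hidden_factors = 1, factor_strength = 0.5, seed = 7)
  sim1 <- simulate_lrn_cascade(cfg1)
  expect_gt(cor(sim1$omics$mrna[1, ], sim1$omics$h3k9ac[1, ]), 0.1)
})

test_that("three-node chain moments match the closed-form covariance", {
  # independent oracle: propagate the covariance of g -> m -> e by hand
  b1 <- 0.6; b2 <- 0.4; s <- 0.5
  tpl <- data.frame(parent = c("g_m", "m"), child = c("m", "e"))
  cfg <- cascade_config(n_samples = 8000, template = tpl,
                        effect_sizes = c("g_m->m" = b1, "m->e" = b2),
                        noise_sd = s, n_hidden_factors = 0, seed = 8)
  sim <- simulate_lrn_cascade(cfg)
  var_m <- b1^2 + s^2                       # parent standardized
  cov_ge_over_sdg <- b1 * b2 / sqrt(var_m)  # cov(std(g), e)
  m <- sim$omics$dnam[1, ]; e <- sim$omics$mrna[1, ]
  g <- sim$genotypes$dosage["gene001.g_m", ]
  expect_equal(var(m), var_m, tolerance = 0.05)
  expect_equal(var(e), b2^2 + s^2, tolerance = 0.05)
  expect_equal(cov(scale(g)[, 1], e), cov_ge_over_sdg, tolerance = 0.05)
})

test_that("the whole dataset is a deterministic function of the config", {
  cfg <- cascade_config(n_samples = 80, n_genes = 2, seed = 9)
  a <- simulate_lrn_cascade(cfg)
  b <- simulate_lrn_cascade(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$omics, b$omics)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$hidden_factors, b$hidden_factors)
})

test_that("DNAm is exported on both latent and Beta scales coherently", {
  sim <- simulate_lrn_cascade(cascade_config(n_samples = 50, seed = 10))
  expect_true(all(sim$omics$dnam_beta > 0 & sim$omics$dnam_beta < 1))
  expect_equal(qlogis(sim$omics$dnam_beta), sim$omics$dnam, tolerance = 1e-12)
})

test_that("true relation labels follow directed-path reachability", {
  sim <- simulate_lrn_cascade(cascade_config(n_samples = 50, seed = 11))
  tr <- sim$true_relations
  key <- function(a, b) tr$label[tr$source == a & tr$reference == b]
  expect_identical(key("m", "p"), "upstream")     # transitive chain path
  expect_identical(key("p", "m"), "downstream")   # symmetric consistency
  expect_identical(key("g_m", "p"), "upstream")
  # disconnected node is independent
  tpl <- data.frame(parent = c("g_m", "g_h"), child = c("m", "h"))
  tpl <- rbind(tpl, data.frame(parent = "m", child = "e"))
  sim2 <- simulate_lrn_cascade(cascade_config(n_samples = 50, template = tpl,
                                              n_hidden_factors = 0, seed = 12))
  tr2 <- sim2$true_relations
  expect_identical(tr2$label[tr2$source == "h" & tr2$reference == "e"],
                   "independent")
  # SNP nodes are roots: never downstream of anything
  for (t in list(tr, tr2)) {
    snp_rows <- t[startsWith(t$source, "g_"), ]
    expect_false(any(snp_rows$label == "downstream"))
  }
})

test_that("relations re-derived from the stored DAG match the stored table", {
  sim <- simulate_lrn_cascade(cascade_config(n_samples = 50, n_genes = 1, seed = 13))
  expect_identical(true_relations(sim$true_dag), sim$true_relations)
})

test_that("phenotype contexts reuse molecular data with fresh noise", {
  sim <- simulate_lrn_cascade(cascade_config(n_samples = 300, n_genes = 2, seed = 14))
  ctx <- simulate_phenotype_contexts(sim, n_contexts = 3, seed = 15)
  expect_length(ctx, 3)
  e <- sim$omics$mrna["gene001", ]
  # every context correlates with the gene's mRNA, contexts differ
  for (k in 1:3) expect_gt(cor(ctx[[k]]["gene001", ], e), 0.4)
  expect_false(identical(ctx[[1]], ctx[[2]]))
})
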