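test_that("node sets validate typing and anchoring invariants", {
  n <- 50
  v <- cbind(p = rnorm(n), e = rnorm(n), m = rnorm(n), g_m = rbinom(n, 2, 0.3))
  ns <- lrn_node_set(v, anchors = c(g_m = "m"))
  expect_s3_class(ns, "lrn_node_set")
  # canonical order: p, e, m, then SNPs
  expect_identical(colnames(ns$values), c("p", "e", "m", "g_m"))
  # a mark without an anchor SNP is rejected
  expect_error(lrn_node_set(v[, c("p", "e", "m")]), "anchor SNP")
  # two e nodes are rejected
  v2 <- cbind(e1 = rnorm(n), e2 = rnorm(n))
  expect_error(lrn_node_set(v2), "exactly one")
  # non-finite values are rejected
  v3 <- v; v3[1, 1] <- NA
  expect_error(lrn_node_set(v3, anchors = c(g_m = "m")), "finite")
})

test_that("the parent mask encodes menus, anchors and root constraints", {
  n <- 40
  set.seed(1)
  v <- cbind(p = rnorm(n), e = rnorm(n),
             `m:a` = rnorm(n), `m:b` = rnorm(n), `h:c` = rnorm(n),
             g_e = rbinom(n, 2, .3), `g_m:a` = rbinom(n, 2, .3),
             `g_m:b` = rbinom(n, 2, .3), `g_h:c` = rbinom(n, 2, .3),
             C_e = rnorm(n), `C_m:a` = rnorm(n))
  ns <- lrn_node_set(v,
    anchors = c(g_e = "e", `g_m:a` = "m:a", `g_m:b` = "m:b", `g_h:c` = "h:c"),
    cov_targets = c(C_e = "e", `C_m:a` = "m:a"))
  mask <- allowed_parent_mask(ns)
  nodes <- colnames(ns$values)
  snps <- nodes[startsWith(nodes, "g_")]
  covs <- nodes[startsWith(nodes, "C_")]
  # SNPs and covariates have no parents at all
  expect_true(all(!mask[snps, ]))
  expect_true(all(!mask[covs, ]))
  # e <-> p bidirectional candidates, resolved by the data
  expect_true(mask["e", "p"] && mask["p", "e"])
  # anchor SNPs parent only their own node and the phenotype
  expect_true(mask["m:a", "g_m:a"]); expect_false(mask["m:b", "g_m:a"])
  expect_true(mask["p", "g_m:a"]);   expect_false(mask["e", "g_m:a"])
  expect_true(mask["e", "g_e"]);     expect_false(mask["m:a", "g_e"])
  # covariates feed only their own feature, never across layers
  expect_true(mask["e", "C_e"]);     expect_false(mask["m:a", "C_e"])
  expect_true(mask["m:a", "C_m:a"]); expect_false(mask["m:b", "C_m:a"])
  # marks of the same class never parent each other (menus exclude m -> m)
  expect_false(mask["m:a", "m:b"]); expect_false(mask["m:b", "m:a"])
  # cross-class marks and phenotype follow the menus
  expect_true(mask["m:a", "h:c"]); expect_true(mask["h:c", "m:a"])
  expect_true(mask["p", "m:a"]);   expect_false(mask["p", "C_e"])
  expect_true(all(!diag(mask)))
})

make_pipeline_fixture <- function(seed = 2) {
  # hand-built mapping tables: gene with 2 eQTMs (one QTL-anchored) and one
  # anchored eQTH
  set.seed(seed)
  n <- 60
  samples <- sprintf("S%03d", 1:n)
  mk <- function(nm) matrix(rnorm(n), 1, dimnames = list(nm, samples))
  expression <- mk("gene1")
  dnam <- rbind(mk("m1"), mk("m2"))
  h3k9ac <- mk("h1")
  dosage <- rbind(s_e = rbinom(n, 2, .3), s_m1 = rbinom(n, 2, .3),
                  s_h1 = rbinom(n, 2, .3))
  colnames(dosage) <- samples
  genotypes <- list(dosage = dosage,
                    info = data.frame(snp = rownames(dosage), chrom = "1",
                                      pos = c(100L, 200L, 300L)))
  qtl_row <- function(feature, variant, sig) data.frame(
    feature = feature, variant = variant, beta = 1, r = 0.5,
    nominal_p = 1e-4, perm_p = 1e-3, n_tested = 3L,
    qvalue = if (sig) 0.01 else 0.5, significant = sig)
  eqtx_row <- function(gene, peak, r, sig) data.frame(
    gene = gene, peak = peak, r = r, p_pair = 1e-4, q_pair = 0.01,
    p_gene = 1e-3, q_gene = 0.01, significant = sig)
  list(
    phenotype = setNames(rnorm(n), samples),
    expression = expression, genotypes = genotypes,
    dnam = dnam, h3k9ac = h3k9ac,
    eqtl = qtl_row("gene1", "s_e", TRUE),
    mqtl = rbind(qtl_row("m1", "s_m1", TRUE), qtl_row("m2", "s_x", FALSE)),
    haqtl = qtl_row("h1", "s_h1", TRUE),
    eqtm = rbind(eqtx_row("gene1", "m1", -0.5, TRUE),
                 eqtx_row("gene1", "m2", 0.4, TRUE)),
    eqth = eqtx_row("gene1", "h1", 0.5, TRUE),
    factor_models = list(mrna = estimate_hidden_factors(rbind(expression, mk("other")), 1),
                         dnam = estimate_hidden_factors(rbind(dnam, mk("pad")), 1),
                         h3k9ac = estimate_hidden_factors(rbind(h3k9ac, mk("pad2")), 1)))
}

test_that("node-set assembly keeps anchored marks and drops QTL-less ones", {
  fx <- make_pipeline_fixture()
  ns <- build_node_set("gene1", fx$phenotype, fx$expression, fx$genotypes,
                       eqtl = fx$eqtl, mqtl = fx$mqtl, haqtl = fx$haqtl,
                       eqtm = fx$eqtm, eqth = fx$eqth,
                       dnam = fx$dnam, h3k9ac = fx$h3k9ac,
                       factor_models = fx$factor_models)
  nodes <- colnames(ns$values)
  expect_setequal(nodes, c("p", "e", "m:m1", "h:h1", "g_e", "g_m:m1",
                           "g_h:h1", "C_e", "C_m:m1", "C_h:h1"))
  expect_false(any(grepl("m2", nodes)))  # eQTM without mQTL excluded
  expect_identical(unname(ns$anchors["g_m:m1"]), "m:m1")
  # deterministic canonical ordering across repeated builds
  ns2 <- build_node_set("gene1", fx$phenotype, fx$expression, fx$genotypes,
                        eqtl = fx$eqtl, mqtl = fx$mqtl, haqtl = fx$haqtl,
                        eqtm = fx$eqtm, eqth = fx$eqth,
                        dnam = fx$dnam, h3k9ac = fx$h3k9ac,
                        factor_models = fx$factor_models)
  expect_identical(colnames(ns$values), colnames(ns2$values))
  expect_identical(ns$values, ns2$values)
})

test_that("genes failing the inclusion criteria raise an explicit signal", {
  fx <- make_pipeline_fixture()
  no_marks <- expect_error(
    build_node_set("gene1", fx$phenotype, fx$expression, fx$genotypes,
                   eqtl = fx$eqtl, dnam = fx$dnam, h3k9ac = fx$h3k9ac),
    class = "lrn_ineligible_gene")
  # relaxed rule admits an eQTL-only gene
  ns <- build_node_set("gene1", fx$phenotype, fx$expression, fx$genotypes,
                       eqtl = fx$eqtl, require = "any")
  expect_setequal(colnames(ns$values), c("p", "e", "g_e"))
})

test_that("node sets built from simulations match the template topology", {
  sim <- simulate_lrn_cascade(cascade_config(n_samples = 100, seed = 3))
  ns <- node_set_from_sim(sim, "gene001")
  expect_setequal(colnames(ns$values), c("p", "e", "m", "g_m"))
  expect_identical(unname(ns$anchors["g_m"]), "m")
  # non-genetic nodes are quantile-normalized (means ~ 0, normal ranks)
  expect_lt(abs(mean(ns$values[, "e"])), 1e-10)
  expect_error(node_set_from_sim(sim, "nope"), "unknown gene")
})
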