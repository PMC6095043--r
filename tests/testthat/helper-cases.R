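# Shared builders for small LRN test cases.

# direct anchored-chain node set g_m -> m -> e -> p without the generator,
# for score/sampler unit tests
chain_node_set <- function(n = 300, effects = c(0.8, 0.8, 0.8),
                           noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  std <- function(v) (v - mean(v)) / sd(v)
  g <- rbinom(n, 2, 0.3)
  m <- effects[1] * std(g) + rnorm(n, 0, noise_sd)
  e <- effects[2] * std(m) + rnorm(n, 0, noise_sd)
  p <- effects[3] * std(e) + rnorm(n, 0, noise_sd)
  v <- cbind(g_m = g,
             m = quantile_normalize(m),
             e = quantile_normalize(e),
             p = quantile_normalize(p))
  lrn_node_set(v, anchors = c(g_m = "m"))
}

# archetype templates for randomized oracle-equivalence cases (<= 5 nodes,
# <= 4 constrained nodes, so exact enumeration stays instant)
case_templates <- list(
  data.frame(parent = c("g_m", "m", "e"), child = c("m", "e", "p")),
  data.frame(parent = c("g_e", "e"), child = c("e", "p")),
  data.frame(parent = c("g_m", "m", "g_h", "h"), child = c("m", "e", "h", "e")),
  data.frame(parent = c("g_h", "h", "e"), child = c("h", "e", "p")),
  data.frame(parent = c("g_m", "m", "e", "g_e"), child = c("m", "e", "p", "e"))
)

# random small node set with data generated under a known template
random_lrn_case <- function(seed, n_samples = 300) {
  set.seed(seed)
  template <- case_templates[[(seed %% length(case_templates)) + 1L]]
  effects <- setNames(round(runif(nrow(template), 0.2, 0.8), 3),
                      paste0(template$parent, "->", template$child))
  cfg <- cascade_config(n_samples = n_samples, n_genes = 1,
                        template = template, effect_sizes = effects,
                        seed = seed + 1000L)
  sim <- simulate_lrn_cascade(cfg)
  list(sim = sim, node_set = node_set_from_sim(sim, "gene001"))
}

# transitive closure by boolean matrix powers (reachability oracle)
closure_oracle <- function(adj) {
  p <- nrow(adj)
  reach <- adj
  for (k in seq_len(p)) reach <- (reach %*% adj > 0) | reach
  reach > 0
}
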