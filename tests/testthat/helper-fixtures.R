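# small shared fixtures, built in code and cached for the session

micro_panel <- function() {
  # the 3-line / 1-marker worked micro-panel: codes 0, 1, 2
  genotype_panel(matrix(c(0, 1, 2), ncol = 1,
                        dimnames = list(c("a", "b", "c"), "m1")))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small structured panel with both traits, reused across test files
small_sim <- function() {
  cached("small_sim", simulate_panel(
    sim_config(n_lines = 60, n_markers = 300, n_genes = 120, seed = 202)))
}

small_bundle <- function() {
  sp <- small_sim()
  cached("small_bundle",
         prediction_bundle(sp$genotypes, sp$phenotypes, sp$transcriptome))
}

random_psd <- function(n, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  crossprod(M) / n
}

# single additive-kernel model on a simulated panel (shared oracle fixture)
make_single_term_model <- function(n = 50, seed = 101, var_g = 1,
                                   var_e = 0.5) {
  set.seed(seed)
  cfg <- sim_config(n_lines = n, n_markers = 200, n_genes = 10, n_envs = 1,
                    var_additive = var_g, var_epistatic = 0, var_gxe = 0,
                    var_residual = var_e, seed = seed)
  gp <- simulate_genotypes(cfg)
  G <- grm_linear(gp)
  ph <- simulate_phenotypes(gp, list(additive = G), cfg)
  obs <- ph$phenotypes[, c("line", "env")]
  model <- model_spec(list(re_term("G", G, genetic = TRUE)), obs = obs)
  list(model = model, y = ph$phenotypes$trait, G = G,
       g_true = ph$true_effects$terms$additive)
}

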