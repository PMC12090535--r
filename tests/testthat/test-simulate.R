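test_that("full inbreeding forbids heterozygotes; zero inbreeding is HWE", {
  cfg1 <- sim_config(n_lines = 80, n_markers = 150, n_genes = 10,
                     inbreeding_f = 1, seed = 3)
  gp1 <- simulate_genotypes(cfg1)
  expect_true(all(gp1$codes %in% c(0, 2)))

  # f = 0: realised heterozygosity approximately 2 p (1 - p) per marker
  cfg0 <- sim_config(n_lines = 600, n_markers = 300, n_genes = 10,
                     inbreeding_f = 0, n_families = 1, seed = 4)
  gp0 <- simulate_genotypes(cfg0)
  het <- colMeans(gp0$codes == 1)
  p <- gp0$allele_freq
  expect_lt(mean(abs(het - 2 * p * (1 - p))), 0.02)
  expect_lt(max(abs(het - 2 * p * (1 - p))), 0.08)

  # determinism under a fixed seed
  gp0b <- simulate_genotypes(cfg0)
  expect_identical(gp0$codes, gp0b$codes)

  expect_error(sim_config(maf_range = c(0.3, 0.2)), "maf_range")
  expect_error(sim_config(var_gxe = -1), "variance")
})

test_that("founder families create within-family relatedness", {
  cfg <- sim_config(n_lines = 60, n_markers = 400, n_genes = 10,
                    n_families = 6, family_relatedness = 0.9, seed = 9)
  G <- unclass(grm_linear(simulate_genotypes(cfg)))
  fam <- rep(1:6, length.out = 60)
  same <- outer(fam, fam, "==") & upper.tri(G)
  diff <- (!outer(fam, fam, "==")) & upper.tri(G)
  expect_gt(mean(G[same]), mean(G[diff]) + 0.5)
})

test_that("transcriptome carries genetic and environmental signal as configured", {
  base <- small_sim()$genotypes

  # pure-noise transcripts: kernel uncorrelated with the GRM
  cfg0 <- sim_config(n_lines = 60, n_markers = 300, n_genes = 150,
                     transcriptome_h2 = 0, transcriptome_env_frac = 0,
                     seed = 21)
  tr0 <- simulate_transcriptome(base, cfg0)
  T0 <- transcriptome_kernel(tr0$abundances$env1)
  G <- grm_linear(base)
  off <- upper.tri(unclass(G))
  r0 <- cor(unclass(T0)[off], unclass(G)[off])
  expect_lt(abs(r0), 0.12)

  # fully genetic, noiseless transcripts: kernel approaches the GRM
  cfg1 <- sim_config(n_lines = 60, n_markers = 300, n_genes = 400,
                     transcriptome_h2 = 1, transcriptome_env_frac = 0,
                     seed = 22)
  tr1 <- simulate_transcriptome(base, cfg1)
  T1 <- transcriptome_kernel(tr1$abundances$env1)
  r1 <- cor(unclass(T1)[off], unclass(G)[off])
  expect_gt(r1, 0.85)

  # environment share: per-gene means differ between environments
  cfg2 <- sim_config(n_lines = 60, n_markers = 300, n_genes = 200,
                     transcriptome_h2 = 0.2, transcriptome_env_frac = 0.6,
                     seed = 23)
  tr2 <- simulate_transcriptome(base, cfg2)
  dmeans <- colMeans(tr2$abundances$env1) - colMeans(tr2$abundances$env2)
  expect_gt(sd(dmeans), 0.3)

  expect_error(sim_config(transcriptome_h2 = 0.7,
                          transcriptome_env_frac = 0.5), "transcriptome")
})

test_that("phenotypes reconstruct exactly from recorded truth", {
  sp <- small_sim()
  te <- sp$true_effects$trait_gxe
  phen <- sp$phenotypes
  li <- match(phen$line, sp$genotypes$line_ids)
  ei <- match(phen$env, names(te$intercepts))
  y_rebuilt <- te$intercepts[ei] + te$noise
  for (eff in te$terms) y_rebuilt <- y_rebuilt + eff[li]
  if (!is.null(te$gxe)) {
    y_rebuilt <- y_rebuilt +
      vapply(seq_along(li), function(i) te$gxe[[ei[i]]][li[i]], numeric(1))
  }
  expect_equal(unname(y_rebuilt), phen$trait_gxe, tolerance = 1e-12)
})

test_that("degenerate and limiting phenotype settings behave as stated", {
  cfg <- sim_config(n_lines = 30, n_markers = 100, n_genes = 10,
                    var_additive = 0, var_epistatic = 0, var_dominance = 0,
                    var_gxe = 0, var_residual = 0, seed = 31)
  gp <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gp, list(), cfg)
  mu <- cfg$intercept + cfg$env_offsets
  expect_equal(sort(unique(ph$phenotypes$trait)), sort(unique(unname(mu))))

  # additive-only: realised narrow-sense h2 near var_a / (var_a + var_e)
  h2_hat <- replicate(12, {
    s <- sample.int(1e6, 1)
    cfga <- sim_config(n_lines = 120, n_markers = 200, n_genes = 10,
                       n_envs = 1, var_additive = 1, var_epistatic = 0,
                       var_gxe = 0, var_residual = 1, seed = s)
    gpa <- simulate_genotypes(cfga)
    G <- grm_linear(gpa)
    pha <- simulate_phenotypes(gpa, list(additive = G), cfga)
    g <- pha$true_effects$terms$additive
    y <- pha$phenotypes$trait
    var(g) / var(y)
  })
  md <- mean(diag(grm_linear(simulate_genotypes(
    sim_config(n_lines = 120, n_markers = 200, n_genes = 10, seed = 1)))))
  expect_equal(mean(h2_hat), md / (md + 1), tolerance = 0.12)

  # G x E reorders lines across environments
  sp <- small_sim()
  w <- tidyr::pivot_wider(sp$phenotypes[, c("line", "env", "trait_gxe")],
                          names_from = "env", values_from = "trait_gxe")
  rc <- cor(w$env1, w$env2, method = "spearman")
  expect_lt(rc, 0.8)

  # dominance inestimable warning under full inbreeding
  cfgd <- sim_config(n_lines = 20, n_markers = 80, n_genes = 10,
                     inbreeding_f = 1, var_dominance = 0.5,
                     var_additive = 0.5, var_epistatic = 0, var_gxe = 0,
                     seed = 33)
  gpd <- simulate_genotypes(cfgd)
  G <- grm_linear(gpd)
  expect_warning(
    simulate_phenotypes(gpd, list(additive = G, dominance = G), cfgd),
    class = "omicblup_dominance_inestimable")
})

test_that("the same seed reproduces an identical panel", {
  cfg <- sim_config(n_lines = 25, n_markers = 60, n_genes = 30, seed = 77)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$genotypes$codes, s2$genotypes$codes)
  expect_identical(s1$abundances, s2$abundances)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("generated effect variances match variance x mean kernel diagonal", {
  devs <- replicate(25, {
    s <- sample.int(1e6, 1)
    cfg <- sim_config(n_lines = 150, n_markers = 150, n_genes = 10,
                      n_envs = 1, var_additive = 2, var_epistatic = 0,
                      var_gxe = 0, var_residual = 0.1, seed = s)
    gp <- simulate_genotypes(cfg)
    G <- grm_linear(gp)
    ph <- simulate_phenotypes(gp, list(additive = G), cfg)
    var(ph$true_effects$terms$additive) / (2 * mean(diag(G)))
  })
  expect_equal(mean(devs), 1, tolerance = 0.25)
})
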