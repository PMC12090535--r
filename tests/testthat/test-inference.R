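test_that("eigendecomposition preserves trace, rank and reconstruction", {
  E1 <- eigendecompose(diag(4))
  expect_equal(E1$values, rep(1, 4))
  expect_equal(E1$rank, 4)

  # rank-1 kernel from the single-marker worked example
  G <- grm_linear(micro_panel())
  Eg <- eigendecompose(G)
  expect_equal(Eg$rank, 1)
  expect_equal(Eg$values[1], 4)   # trace 2 + 0 + 2

  K <- random_psd(20, seed = 11)
  Ek <- eigendecompose(K)
  expect_equal(sum(Ek$values), sum(diag(K)), tolerance = 1e-10)
  Krec <- Ek$vectors %*% (Ek$values * t(Ek$vectors))
  expect_equal(Krec, K, tolerance = 1e-8, ignore_attr = TRUE)

  M <- matrix(rnorm(16), 4)
  expect_error(eigendecompose(M), "asymmetric")
})

test_that("with fixed variances the sampler matches the closed-form BLUP", {
  d <- make_single_term_model(n = 40, seed = 55, var_g = 1, var_e = 0.5)
  fit <- gibbs_fit(d$y, d$model, iterations = 3000, burn_in = 500, thin = 2,
                   seed = 7, fix_variances = list(G = 1, residual = 0.5))
  # closed-form mixed-model solution with the same fixed variances
  n <- length(d$y)
  K <- unclass(d$G)
  mu_hat <- mean(colMeans(fit$intercept_draws))
  u_star <- K %*% solve(K + diag(0.5 / 1, n), d$y - mu_hat)
  expect_gt(cor(fit$effect_means$G, as.vector(u_star)), 0.99)
  # and the fit is reproducible under the same seed
  fit2 <- gibbs_fit(d$y, d$model, iterations = 3000, burn_in = 500, thin = 2,
                    seed = 7, fix_variances = list(G = 1, residual = 0.5))
  expect_identical(fit$variance_draws, fit2$variance_draws)
  expect_identical(fit$effect_means, fit2$effect_means)
})

test_that("degenerate shrinkage collapses predictions to the intercept", {
  d <- make_single_term_model(n = 30, seed = 66)
  fit <- gibbs_fit(d$y, d$model, iterations = 800, burn_in = 200, thin = 1,
                   seed = 2, fix_variances = list(G = 1e-9))
  expect_lt(max(abs(fit$effect_means$G)), 1e-3)
  mu_hat <- mean(fit$intercept_draws)
  expect_lt(max(abs(fit$fitted_mean - mu_hat)), 0.01)
})

test_that("eigen-transformed and direct samplers agree on variance posteriors", {
  d <- make_single_term_model(n = 30, seed = 77, var_g = 1, var_e = 1)
  f_eig <- gibbs_fit(d$y, d$model, iterations = 6000, burn_in = 1000,
                     thin = 2, seed = 11, method = "eigen", ess_warn = 0)
  f_dir <- gibbs_fit(d$y, d$model, iterations = 6000, burn_in = 1000,
                     thin = 2, seed = 12, method = "direct", ess_warn = 0)
  for (comp in c("G", "residual")) {
    m1 <- mean(f_eig$variance_draws[, comp])
    m2 <- mean(f_dir$variance_draws[, comp])
    se1 <- sd(f_eig$variance_draws[, comp]) / sqrt(f_eig$ess[comp])
    se2 <- sd(f_dir$variance_draws[, comp]) / sqrt(f_dir$ess[comp])
    expect_lt(abs(m1 - m2), 3 * sqrt(se1^2 + se2^2) + 1e-8)
  }
})

test_that("credible intervals cover generative variances at near-nominal rate", {
  hits <- vapply(1:40, function(s) {
    d <- make_single_term_model(n = 40, seed = 4000 + s, var_g = 1,
                                var_e = 1)
    fit <- gibbs_fit(d$y, d$model, iterations = 1200, burn_in = 300,
                     thin = 2, seed = s, ess_warn = 0)
    ti <- tidy(fit, conf.level = 0.9)
    covered <- ti$conf.low <= 1 & ti$conf.high >= 1
    c(G = covered[ti$term == "G"], res = covered[ti$term == "residual"])
  }, c(G = NA, res = NA))
  # nominal 90%; binomial noise over 40 replicates
  expect_gte(mean(hits["G", ]), 0.7)
  expect_gte(mean(hits["res", ]), 0.7)
})

test_that("posterior_predict is consistent in-sample and under masking", {
  d <- make_single_term_model(n = 40, seed = 88, var_e = 0.05)
  # duplicate-line oracle: line 2 masked, its genotype duplicates line 1
  gp <- d$model$obs
  y <- d$y
  K <- unclass(d$model$terms$G$kernel)
  K2 <- K
  K2[2, ] <- K[1, ]; K2[, 2] <- K[, 1]; K2[2, 2] <- K[1, 1]
  Kdup <- kernel_matrix(K2, kind = "G", axis_ids = rownames(K),
                        check = FALSE)
  mdup <- model_spec(list(re_term("G", Kdup, genetic = TRUE)), obs = gp)
  y_mask <- y
  y_mask[2] <- NA
  fit <- gibbs_fit(y_mask, mdup, iterations = 2500, burn_in = 500, thin = 2,
                   seed = 3, ess_warn = 0)
  pp <- posterior_predict(fit)
  expect_equal(nrow(pp), 40)
  expect_equal(pp$.pred[2], pp$.pred[1], tolerance = 0.05)
  # in-sample predictions track observed values when noise is tiny
  expect_gt(cor(pp$.pred[-2], y[-2]), 0.97)
})

test_that("GEBVs sum genetic terms only and permute with line labels", {
  sp <- small_sim()
  b <- small_bundle()
  m <- build_scenario("G_T", b)
  fit <- gibbs_fit(sp$phenotypes$trait_additive, m, iterations = 600,
                   burn_in = 200, thin = 2, seed = 5, ess_warn = 0)
  gb <- gebv(fit)
  expect_equal(nrow(gb), nrow(sp$genotypes$codes))
  # excludes T by default: equals the per-line mean of the G term alone
  li <- split(fit$effect_means$G, as.character(m$obs$line))
  expect_equal(gb$gebv[match(names(li), gb$line)],
               unname(vapply(li, mean, numeric(1))))
  gb_both <- gebv(fit, terms = c("G", "T"))
  expect_false(isTRUE(all.equal(gb$gebv, gb_both$gebv)))

  # a transcriptome-only model has no genetic term
  mt <- build_scenario("RKHS_T", b)
  ft <- gibbs_fit(sp$phenotypes$trait_additive, mt, iterations = 300,
                  burn_in = 100, thin = 1, seed = 5, ess_warn = 0)
  expect_error(gebv(ft), "no genetic term")

  # permutation equivariance: relabelled observations give permuted GEBVs
  perm <- sample(nrow(sp$phenotypes))
  obs_p <- sp$phenotypes[perm, ]
  mp <- model_spec(list(re_term("G", grm_linear(sp$genotypes),
                                genetic = TRUE)), obs = obs_p)
  fp <- gibbs_fit(sp$phenotypes$trait_additive[perm], mp, iterations = 600,
                  burn_in = 200, thin = 2, seed = 9, ess_warn = 0)
  m0 <- model_spec(list(re_term("G", grm_linear(sp$genotypes),
                                genetic = TRUE)), obs = sp$phenotypes)
  f0 <- gibbs_fit(sp$phenotypes$trait_additive, m0, iterations = 600,
                  burn_in = 200, thin = 2, seed = 9, ess_warn = 0)
  g1 <- gebv(f0); g2 <- gebv(fp)
  expect_equal(g1$line, g2$line)
  expect_gt(cor(g1$gebv, g2$gebv), 0.98)
})

test_that("GEBV accuracy grows with chain length to a plateau", {
  d <- make_single_term_model(n = 50, seed = 99, var_g = 1, var_e = 0.3)
  accs <- vapply(c(60, 400, 2000), function(it) {
    fit <- gibbs_fit(d$y, d$model, iterations = it,
                     burn_in = floor(it / 3), thin = 1, seed = 4,
                     ess_warn = 0)
    cor(gebv(fit)$gebv, d$g_true)
  }, numeric(1))
  expect_gt(accs[3], 0.85)
  expect_gt(accs[3], accs[1] - 0.02)
})

test_that("chain bookkeeping and input validation hold", {
  d <- make_single_term_model(n = 20, seed = 111)
  fit <- gibbs_fit(d$y, d$model, iterations = 1000, burn_in = 400, thin = 3,
                   seed = 1, ess_warn = 0)
  expect_equal(nrow(fit$variance_draws), 200)   # (1000 - 400) / 3
  expect_true(all(fit$variance_draws > 0))
  expect_error(gibbs_fit(d$y, d$model, iterations = 100, burn_in = 100),
               "burn_in")
  expect_error(gibbs_fit(d$y[-1], d$model), "length")
  expect_error(gibbs_fit(rep(NA_real_, 20), d$model), "no observed")
  g <- glance(fit)
  expect_equal(g$nobs, 20)
  expect_equal(g$draws, 200)
})
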