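test_that("genotype centring follows W = X - 2p and drops monomorphic markers", {
  gp <- micro_panel()
  W <- center_genotypes(gp)
  expect_equal(gp$allele_freq[["m1"]], 0.5)
  expect_equal(as.numeric(W), c(-1, 0, 1))

  # all-zero column flagged and dropped
  gp2 <- genotype_panel(cbind(m1 = c(0, 1, 2), m2 = c(0, 0, 0)))
  expect_warning(W2 <- center_genotypes(gp2), class = "omicblup_monomorphic")
  expect_equal(colnames(W2), "m1")

  # {-1,0,1} dialect auto-shifts to the same result
  gp3 <- genotype_panel(matrix(c(-1, 0, 1), ncol = 1,
                               dimnames = list(c("a", "b", "c"), "m1")))
  expect_equal(unname(center_genotypes(gp3)), unname(W),
               ignore_attr = TRUE)

  # ambiguous value set is refused, not guessed
  expect_error(genotype_panel(cbind(m1 = c(0, 1, 0))), "ambiguous")
})

test_that("GRM matches the hand-computed single-marker example", {
  G <- grm_linear(micro_panel())
  expect_equal(unclass(G),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
               ignore_attr = "kind")
  # duplicated line: off-diagonal equals the shared diagonal
  gp <- genotype_panel(rbind(a = c(0, 2, 1), b = c(0, 2, 1), c = c(2, 0, 0)))
  Gd <- grm_linear(gp)
  expect_equal(Gd["a", "b"], Gd["a", "a"])
  expect_error(grm_linear(genotype_panel(cbind(m1 = c(2, 2, 2)))),
               "monomorphic")
})

test_that("GRM is invariant to marker and line permutation", {
  sp <- small_sim()
  gp <- sp$genotypes
  G <- unclass(grm_linear(gp))
  set.seed(5)
  pm <- sample(ncol(gp$codes))
  pl <- sample(nrow(gp$codes))
  gp_m <- genotype_panel(gp$codes[, pm])
  gp_l <- genotype_panel(gp$codes[pl, ])
  expect_equal(unclass(grm_linear(gp_m)), G, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(grm_linear(gp_l))[gp$line_ids, gp$line_ids],
               unclass(G)[gp$line_ids, gp$line_ids], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("epistasis kernel is the Hadamard square and stays PSD", {
  G <- grm_linear(micro_panel())
  E <- epistasis_kernel(G)
  expect_equal(unname(unclass(E)),
               matrix(c(4, 0, 4, 0, 0, 0, 4, 0, 4), 3), ignore_attr = TRUE)
  I5 <- kernel_matrix(diag(5))
  expect_equal(unname(unclass(epistasis_kernel(I5))), diag(5),
               ignore_attr = TRUE)
  # Hadamard products of random PSD kernels keep the eigenvalue floor
  for (s in 1:5) {
    K <- random_psd(12, seed = s)
    H <- K * K
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("dominance kernel recodes heterozygosity and needs heterozygotes", {
  # codes (0,1,2) -> homozygosity indicator (1,0,1)
  gp <- genotype_panel(matrix(c(0, 1, 2, 1, 0, 1), ncol = 2,
                              dimnames = list(c("a", "b", "c"),
                                              c("m1", "m2"))))
  A <- dominance_kernel(gp)
  expect_equal(mean(diag(A)), 1)
  # lines a and c share the same heterozygosity pattern -> maximal entry
  expect_equal(A["a", "c"], A["a", "a"])
  expect_gt(A["a", "c"], A["a", "b"])

  inbred <- genotype_panel(cbind(m1 = c(0, 2, 2), m2 = c(2, 0, 2)))
  expect_error(dominance_kernel(inbred),
               class = "omicblup_no_heterozygotes")
})

test_that("transcriptome kernel standardises genes and scales the diagonal", {
  # two identical expression profiles -> entry equals shared diagonal
  ab <- rbind(a = c(1, 5, 2), b = c(1, 5, 2), c = c(4, 0, 1))
  Tk <- transcriptome_kernel(ab)
  expect_equal(Tk["a", "b"], Tk["a", "a"])
  expect_equal(mean(diag(Tk)), 1)

  # abundances equal to the centred genotype matrix reproduce the GRM
  sp <- small_sim()
  W <- suppressWarnings(center_genotypes(sp$genotypes))
  Tg <- transcriptome_kernel(W)
  G <- grm_linear(sp$genotypes)
  expect_gt(cor(as.vector(unclass(Tg) / mean(diag(Tg))),
                as.vector(unclass(G) / mean(diag(G)))), 0.99)

  # single standard-scaled gene: rank-1 kernel
  T1 <- transcriptome_kernel(cbind(g1 = c(-1, 0, 1)))
  ev <- eigen(unclass(T1), only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8), 1)
  expect_error(transcriptome_kernel(cbind(g1 = c(1, 1, 1))), "zero variance")
})

test_that("gaussian kernel follows exp(-d2/h) with unit diagonal", {
  K <- gaussian_kernel(rbind(a = c(0, 0), b = c(3, 4)), h = 25)
  expect_equal(K["a", "b"], exp(-1))
  expect_equal(diag(unclass(K)), c(a = 1, b = 1))
  # identical rows -> 1; h -> Inf -> all entries -> 1
  K2 <- gaussian_kernel(rbind(a = c(1, 2), b = c(1, 2)), h = 3)
  expect_equal(K2["a", "b"], 1)
  K3 <- gaussian_kernel(rbind(a = c(0, 0), b = c(3, 4)), h = 1e12)
  expect_gt(K3["a", "b"], 0.999999)
  expect_error(gaussian_kernel(rbind(c(0, 0), c(1, 1)), h = -1), "positive")

  # monotone: non-increasing in distance, non-decreasing in h
  X <- rbind(a = 0, b = 1, c = 5)
  K4 <- gaussian_kernel(X, h = 4)
  expect_gt(K4["a", "b"], K4["a", "c"])
  K5 <- gaussian_kernel(X, h = 8)
  expect_true(all(unclass(K5) >= unclass(K4) - 1e-12))

  # default bandwidth: median of nonzero pairwise squared distances, logged
  K6 <- gaussian_kernel(X)
  expect_equal(attr(K6, "bandwidth"), median(c(1, 25, 16)))
})

test_that("incidence matrix reproduces the printed 3x10 worked example", {
  groups <- rep(c("l1", "l2", "l3"), times = c(5, 3, 2))
  Z <- incidence_matrix(groups)
  expect_equal(dim(Z), c(10L, 3L))
  expect_equal(unname(colSums(Z)), c(5, 3, 2))
  expect_true(all(rowSums(Z) == 1))
  # the printed transpose: rows of Z' are 1111100000 / 0000011100 / 0000000011
  expect_equal(unname(t(unclass(Z))),
               rbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                     c(0, 0, 0, 0, 0, 1, 1, 1, 0, 0),
                     c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1)))

  # one observation per line -> identity
  Zi <- incidence_matrix(c("a", "b", "c"))
  expect_equal(unname(unclass(Zi)), diag(3))
  expect_error(incidence_matrix(c("a", "zz"), levels = c("a", "b")),
               "not mapped")
})

test_that("GxE block kernel zeroes cross-environment blocks", {
  sp <- small_sim()
  G <- grm_linear(sp$genotypes)
  lines <- sp$genotypes$line_ids[1:10]
  obs <- c(lines, lines)
  env <- rep(c("e1", "e2"), each = 10)
  ids <- sprintf("o%02d", seq_along(obs))
  Zg <- incidence_matrix(setNames(obs, ids), levels = lines)
  Ze <- incidence_matrix(setNames(env, ids), levels = c("e1", "e2"))
  K <- gxe_block_kernel(G[lines, lines], Zg, Ze)
  Gsub <- unclass(G)[lines, lines]
  expect_equal(unname(unclass(K)[1:10, 1:10]), unname(Gsub))
  expect_equal(unname(unclass(K)[11:20, 11:20]), unname(Gsub))
  expect_true(all(unclass(K)[1:10, 11:20] == 0))

  # single environment: reduces to Zg G Zg'
  Ze1 <- incidence_matrix(setNames(rep("e1", 20), ids), levels = "e1")
  K1 <- gxe_block_kernel(G[lines, lines], Zg, Ze1)
  expect_equal(unclass(K1), Zg %*% Gsub %*% t(Zg), ignore_attr = TRUE)

  Zbad <- Ze[c(2:20, 1), ]
  expect_error(gxe_block_kernel(G[lines, lines], Zg, Zbad), "ordering")
})

test_that("kernel constructor validates symmetry, ids and the PSD floor", {
  M <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(kernel_matrix(M), "symmetric")
  expect_error(kernel_matrix(diag(2), axis_ids = c("a", "a")), "unique")
  K <- random_psd(8, seed = 3)
  expect_silent(check_psd(kernel_matrix(K)))
  bad <- K - diag(1, 8)
  expect_error(check_psd(bad), "not PSD")
  # in-tolerance negative eigenvalues are repairable
  ev <- eigen(K, symmetric = TRUE)
  vals <- ev$values
  vals[8] <- -1e-12
  K2 <- ev$vectors %*% (vals * t(ev$vectors))
  K2 <- (K2 + t(K2)) / 2
  expect_warning(rep_K <- check_psd(kernel_matrix(K2), repair = TRUE),
                 class = "omicblup_psd_repair")
  expect_gte(min(eigen(rep_K, only.values = TRUE)$values), 0)
})
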