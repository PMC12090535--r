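#' Configuration for the synthetic wheat-panel generator
#'
#' Bundles every knob of the generator: panel dimensions, inbreeding level,
#' allele-frequency range, trait variance components, and how much of the
#' transcript variance is driven by genotype and by environment. Defaults
#' emulate an inbred hexaploid wheat diversity panel: 286 lines genotyped at
#' 33,174 biallelic SNPs with abundances for 44,054 transcripts, grown in two
#' contrasting environments. Variance components are on the squared scale of
#' the trait; their defaults describe a strongly environment-interactive
#' trait (small additive share, dominant G x E share) such as flowering time
#' under contrasting photoperiods.
#'
#' Seed discipline: `simulate_genotypes()` seeds the base RNG at `seed`,
#' `simulate_transcriptome()` at `seed + 1`, and `simulate_phenotypes()` at
#' `seed + 2` (overridable), so each stage is individually reproducible.
#'
#' @param n_lines,n_markers,n_genes,n_envs,reps_per_env Panel dimensions.
#' @param inbreeding_f Inbreeding coefficient `f` in `[0,1]`; heterozygote
#'   frequency is `2p(1-p)(1-f)`.
#' @param maf_range Minor-allele-frequency interval, bounds in `(0, 0.5]`.
#' @param var_additive,var_epistatic,var_dominance,var_gxe,var_residual
#'   Generative variance components (trait units squared).
#' @param transcriptome_h2 Fraction of each transcript's variance driven by
#'   genotype (stable across environments).
#' @param transcriptome_env_frac Fraction driven by environment: split
#'   equally between an environment main shift and a genotype-by-environment
#'   interaction component. `transcriptome_h2 + transcriptome_env_frac`
#'   must not exceed 1.
#' @param intercept Trait intercept (e.g. ~100 days for flowering,
#'   ~90 cm for height).
#' @param env_offsets Per-environment additive shifts on the intercept;
#'   recycled/truncated to `n_envs`.
#' @param gxe_relatedness_share Fraction of the G x E effect's covariance
#'   carried by the genomic relationship structure; the remainder is
#'   line-idiosyncratic (environment-specific genetic effects driven by
#'   individual loci are only partly captured by genome-wide relatedness).
#' @param gxe_structure `"sensitivity"` (default): the G x E effect is a
#'   genotype-specific reaction-norm slope multiplied by a centred
#'   environment contrast -- lines reorder between contrasting environments
#'   (late under short days, early under long days) while their
#'   across-environment mean carries no interaction signal. `"independent"`:
#'   an independent draw per environment (exchangeable environments).
#' @param n_families Founder families giving the panel its relatedness
#'   structure (a diversity panel is a mixture of related material, and
#'   without relatedness genomic prediction carries no cross-line signal);
#'   `0` or `1` gives an unstructured panel of independent lines.
#' @param family_relatedness Probability that a line copies its family
#'   founder's code at a marker (otherwise an independent draw from the same
#'   marker distribution); controls within-family relatedness without
#'   changing the marginal genotype distribution.
#' @param seed Base RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 286, n_markers = 33174, n_genes = 44054,
                       n_envs = 2, reps_per_env = 1,
                       inbreeding_f = 0.9, maf_range = c(0.05, 0.5),
                       var_additive = 0.15, var_epistatic = 0.05,
                       var_dominance = 0, var_gxe = 3, var_residual = 0.4,
                       transcriptome_h2 = 0.4, transcriptome_env_frac = 0.3,
                       intercept = 100, env_offsets = NULL,
                       gxe_relatedness_share = 1,
                       gxe_structure = c("sensitivity", "independent"),
                       n_families = 25, family_relatedness = 0.9,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
              n_genes = as.integer(n_genes), n_envs = as.integer(n_envs),
              reps_per_env = as.integer(reps_per_env),
              inbreeding_f = inbreeding_f, maf_range = maf_range,
              var_additive = var_additive, var_epistatic = var_epistatic,
              var_dominance = var_dominance, var_gxe = var_gxe,
              var_residual = var_residual,
              transcriptome_h2 = transcriptome_h2,
              transcriptome_env_frac = transcriptome_env_frac,
              intercept = intercept,
              env_offsets = env_offsets %||% seq(0, by = 5,
                                                 length.out = n_envs),
              gxe_relatedness_share = gxe_relatedness_share,
              gxe_structure = match.arg(gxe_structure),
              n_families = as.integer(n_families),
              family_relatedness = family_relatedness,
              seed = as.integer(seed))
  vars <- c("var_additive", "var_epistatic", "var_dominance", "var_gxe",
            "var_residual")
  if (any(unlist(cfg[vars]) < 0)) abort("variance components must be >= 0")
  if (cfg$n_envs < 1) abort("n_envs must be >= 1")
  if (length(cfg$maf_range) != 2 || diff(cfg$maf_range) < 0 ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    abort("maf_range must be a non-empty interval within (0, 0.5]")
  }
  if (cfg$inbreeding_f < 0 || cfg$inbreeding_f > 1) {
    abort("inbreeding_f must lie in [0,1]")
  }
  if (cfg$transcriptome_h2 < 0 || cfg$transcriptome_env_frac < 0 ||
      cfg$transcriptome_h2 + cfg$transcriptome_env_frac > 1) {
    abort("transcriptome_h2 + transcriptome_env_frac must lie in [0,1]")
  }
  if (cfg$family_relatedness < 0 || cfg$family_relatedness > 1) {
    abort("family_relatedness must lie in [0,1]")
  }
  if (cfg$gxe_relatedness_share < 0 || cfg$gxe_relatedness_share > 1) {
    abort("gxe_relatedness_share must lie in [0,1]")
  }
  cfg$env_offsets <- rep_len(cfg$env_offsets, cfg$n_envs)
  structure(cfg, class = "sim_config")
}

env_labels <- function(n_envs) sprintf("env%d", seq_len(n_envs))

#' Simulate biallelic genotypes for a partially inbred, structured panel
#'
#' Draws one allele frequency per marker uniformly from `maf_range`, then
#' samples genotype codes with heterozygote probability `2p(1-p)(1-f)` and
#' the inbreeding excess `f p(1-p)` placed on each homozygote class, so the
#' realised inbreeding matches the configured `f` (and the GRM mean diagonal
#' lands at `1 + f`). Relatedness structure: lines belong to founder
#' families; at each marker a line copies its founder's code with
#' probability `family_relatedness` and otherwise draws independently from
#' the same marker distribution -- within-family relatedness without
#' altering the marginal genotype distribution. Markers that come out
#' monomorphic are resampled.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  l <- cfg$n_lines; m <- cfg$n_markers; f <- cfg$inbreeding_f
  nf <- max(1L, min(cfg$n_families, l))
  fam <- rep(seq_len(nf), length.out = l)
  rho <- if (nf > 1) cfg$family_relatedness else 0
  draw_codes <- function(nn, P2, P1) {
    mm <- length(P2)
    u <- matrix(runif(nn * mm), nn, mm)
    (u < rep(P2, each = nn)) * 2 +
      (u >= rep(P2, each = nn) & u < rep(P2 + P1, each = nn)) * 1
  }
  draw <- function(mm) {
    p <- runif(mm, cfg$maf_range[1], cfg$maf_range[2])
    P2 <- p^2 + f * p * (1 - p)
    P1 <- 2 * p * (1 - p) * (1 - f)
    founders <- draw_codes(nf, P2, P1)
    fresh <- draw_codes(l, P2, P1)
    copy <- matrix(runif(l * mm) < rho, l, mm)
    ifelse(copy, founders[fam, , drop = FALSE], fresh)
  }
  X <- draw(m)
  for (it in 1:50) {
    mono <- apply(X, 2, function(x) length(unique(x)) == 1)
    if (!any(mono)) break
    X[, mono] <- draw(sum(mono))
  }
  dimnames(X) <- list(sprintf("L%03d", seq_len(l)),
                      sprintf("M%05d", seq_len(m)))
  genotype_panel(X)
}

#' Simulate per-environment transcript abundances
#'
#' Each gene's abundance is built on a continuous normalised scale as the sum
#' of (i) a genetic score -- a linear combination of a small random subset of
#' centred marker codes, identical across environments, variance share
#' `transcriptome_h2`; (ii) an environment main shift and (iii) an
#' environment-specific genetic interaction score, together carrying variance
#' share `transcriptome_env_frac` (split equally); and (iv) Gaussian noise
#' for the remainder. Abundances therefore differ across environments and the
#' transcriptome carries G, E and G x E signal, mirroring its role as an
#' endophenotype between genome and trait.
#'
#' @param panel A [genotype_panel()].
#' @param cfg A [sim_config()].
#' @param n_qtl_per_gene Markers feeding each gene's genetic score.
#' @return List of class `sim_transcriptome` with `abundances` (named list of
#'   lines x genes matrices, one per environment), `genetic_score` and
#'   `gxe_score` component matrices (ground truth for mediation), and the
#'   variance shares used.
#' @export
simulate_transcriptome <- function(panel, cfg, n_qtl_per_gene = 10) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  h2 <- cfg$transcriptome_h2
  envf <- cfg$transcriptome_env_frac
  l <- nrow(panel$codes); ng <- cfg$n_genes
  W <- suppressWarnings(center_genotypes(panel))
  m <- ncol(W)
  envs <- env_labels(cfg$n_envs)
  unit_scale <- function(x) {
    s <- sd(x)
    if (s > 0) x / s else x
  }
  # shared genetic scores (l x genes)
  Ag <- matrix(0, l, ng)
  for (g in seq_len(ng)) {
    idx <- sample.int(m, min(n_qtl_per_gene, m))
    Ag[, g] <- unit_scale(W[, idx, drop = FALSE] %*% rnorm(length(idx)))
  }
  share_env <- envf / 2
  share_gxe <- envf / 2
  share_noise <- max(0, 1 - h2 - envf)
  Bg <- vector("list", cfg$n_envs)
  abund <- vector("list", cfg$n_envs)
  for (j in seq_len(cfg$n_envs)) {
    B <- matrix(0, l, ng)
    if (share_gxe > 0) {
      for (g in seq_len(ng)) {
        idx <- sample.int(m, min(n_qtl_per_gene, m))
        B[, g] <- unit_scale(W[, idx, drop = FALSE] %*% rnorm(length(idx)))
      }
    }
    Bg[[j]] <- B * sqrt(share_gxe)
    delta <- if (share_env > 0) rnorm(ng, sd = sqrt(share_env)) else numeric(ng)
    noise <- matrix(rnorm(l * ng, sd = sqrt(share_noise)), l, ng)
    A <- Ag * sqrt(h2) + Bg[[j]] +
      matrix(delta, l, ng, byrow = TRUE) + noise
    dimnames(A) <- list(panel$line_ids, sprintf("gene%05d", seq_len(ng)))
    abund[[j]] <- A
  }
  names(abund) <- names(Bg) <- envs
  structure(list(abundances = abund,
                 genetic_score = Ag * sqrt(h2),
                 gxe_score = Bg,
                 shares = c(genetic = h2, env = share_env, gxe = share_gxe,
                            noise = share_noise)),
            class = "sim_transcriptome")
}

#' Average abundances across environments
#'
#' Line-level abundance matrix used to build a single transcriptome kernel
#' when the model has one T term (the usual case).
#' @param trans A `sim_transcriptome` or a list of per-environment matrices.
#' @return lines x genes matrix.
#' @export
pool_abundances <- function(trans) {
  mats <- if (inherits(trans, "sim_transcriptome")) trans$abundances else trans
  Reduce(`+`, mats) / length(mats)
}

draw_mvn <- function(n, K) {
  ev <- eigen(unclass(K), symmetric = TRUE)
  vals <- ev$values
  if (min(vals) < -1e-8 * max(abs(vals), 1e-12)) {
    abort("kernel is not PSD (beyond tolerance); cannot draw effects")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(vals, 0)), n)
  as.vector(L %*% rnorm(n))
}

#' Simulate phenotypes from kernel-distributed random effects
#'
#' Generative mirror of the full model `y = mu + g + g_ep + g_a + gE + e`:
#' each requested random-effect vector is drawn from a zero-mean multivariate
#' Gaussian with covariance (variance component x kernel); the G x E effect
#' is drawn independently per environment from the `gxe` kernel (the
#' multi-environment single-variance structure); replicate observations are
#' expanded through incidence matrices and iid Gaussian noise is added.
#' Ground truth (effect vectors, noise, variances) is recorded so parameter
#' recovery is testable.
#'
#' @param panel A [genotype_panel()].
#' @param kernels Named list of line-level `kernel_matrix` objects; recognised
#'   names `additive`, `epistatic`, `dominance`, `gxe` (for `gxe` a single
#'   kernel or one per environment). Only kernels whose variance component in
#'   `cfg` is positive need be supplied.
#' @param cfg A [sim_config()].
#' @param trait Name for the trait column (default `"trait"`).
#' @param seed RNG seed; defaults to `cfg$seed + 2`.
#' @return List of class `sim_phenotypes`: `phenotypes` tibble
#'   (`line`, `env`, `rep`, `<trait>`) and `true_effects` (per-term vectors,
#'   per-observation noise, intercepts, variance components).
#' @export
simulate_phenotypes <- function(panel, kernels, cfg, trait = "trait",
                                seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  set.seed(seed %||% (cfg$seed + 2L))
  l <- nrow(panel$codes)
  envs <- env_labels(cfg$n_envs)
  if (cfg$inbreeding_f >= 1 && cfg$var_dominance > 0) {
    warn(paste("inbreeding_f = 1: the heterozygosity design is constant and",
               "dominance variance is inestimable"),
         class = "omicblup_dominance_inestimable")
  }
  need <- function(nm) {
    if (is.null(kernels[[nm]])) {
      abort(sprintf("variance for '%s' is positive but no kernel supplied", nm))
    }
    kernels[[nm]]
  }
  eff <- list()
  if (cfg$var_additive > 0) {
    eff$additive <- sqrt(cfg$var_additive) * draw_mvn(l, need("additive"))
  }
  if (cfg$var_epistatic > 0) {
    eff$epistatic <- sqrt(cfg$var_epistatic) * draw_mvn(l, need("epistatic"))
  }
  if (cfg$var_dominance > 0) {
    eff$dominance <- sqrt(cfg$var_dominance) * draw_mvn(l, need("dominance"))
  }
  gE <- NULL
  if (cfg$var_gxe > 0) {
    kg <- need("gxe")
    if (cfg$gxe_structure == "sensitivity" && cfg$n_envs > 1) {
      if (!inherits(kg, "kernel_matrix")) kg <- kg[[1]]
      slope <- sqrt(cfg$var_gxe) * draw_mvn(l, kg)
      cj <- seq_len(cfg$n_envs) - mean(seq_len(cfg$n_envs))
      cj <- cj / sqrt(mean(cj^2))   # unit mean square: var per env preserved
      gE <- lapply(cj, function(c) c * slope)
    } else {
      if (inherits(kg, "kernel_matrix")) kg <- rep(list(kg), cfg$n_envs)
      gE <- lapply(seq_len(cfg$n_envs), function(j) {
        sqrt(cfg$var_gxe) * draw_mvn(l, kg[[j]])
      })
    }
    names(gE) <- envs
  }
  g_line <- Reduce(`+`, c(list(rep(0, l)), eff))
  obs <- tidyr::expand_grid(env = envs, rep = seq_len(cfg$reps_per_env),
                            line = panel$line_ids)
  mu_j <- cfg$intercept + cfg$env_offsets
  names(mu_j) <- envs
  li <- match(obs$line, panel$line_ids)
  ei <- match(obs$env, envs)
  noise <- rnorm(nrow(obs), sd = sqrt(cfg$var_residual))
  y <- mu_j[ei] + g_line[li] + noise
  if (!is.null(gE)) {
    y <- y + vapply(seq_len(nrow(obs)), function(i) gE[[ei[i]]][li[i]],
                    numeric(1))
  }
  phen <- obs
  phen[[trait]] <- as.numeric(y)
  structure(list(phenotypes = tibble::as_tibble(phen),
                 true_effects = list(terms = eff, gxe = gE, noise = noise,
                                     intercepts = mu_j,
                                     variances = c(
                                       additive = cfg$var_additive,
                                       epistatic = cfg$var_epistatic,
                                       dominance = cfg$var_dominance,
                                       gxe = cfg$var_gxe,
                                       residual = cfg$var_residual))),
            class = "sim_phenotypes")
}

#' Simulate a complete panel with two contrasting traits
#'
#' End-to-end generator: genotypes, per-environment transcript abundances,
#' and two traits on the same panel --
#' `trait_additive`, a mostly additive trait (genetic signal drawn from the
#' GRM, no environment interaction; think height), and `trait_gxe`, a
#' strongly environment-interactive trait drawn from the full generative
#' model (additive from G, epistatic from G#G, and an independent per
#' environment G x E effect from G under the multi-environment
#' single-variance structure; think flowering time under contrasting
#' photoperiods). Because the transcriptome's genetic scores are themselves
#' built from the markers, the transcriptome kernel approximates the genomic
#' and G x E structure without the trait being drawn from it -- the
#' endophenotype channel the generator emulates.
#'
#' @param cfg A [sim_config()]. `var_*` components apply to `trait_gxe`;
#'   `trait_additive` uses `var_additive = 1`, `var_gxe = 0` and the same
#'   residual variance.
#' @return List of class `sim_panel`: `genotypes`, `transcriptome`,
#'   `abundances` (pooled lines x genes), `phenotypes` (tibble with both
#'   traits), `true_effects` per trait, and `config`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  trans <- simulate_transcriptome(geno, cfg)
  G <- grm_linear(geno)
  add_cfg <- cfg
  add_cfg$var_additive <- 1
  add_cfg$var_epistatic <- 0
  add_cfg$var_dominance <- 0
  add_cfg$var_gxe <- 0
  ph_add <- simulate_phenotypes(geno, list(additive = G), add_cfg,
                                trait = "trait_additive",
                                seed = cfg$seed + 2L)
  a <- cfg$gxe_relatedness_share
  Kge <- kernel_matrix(a * unclass(G) +
                         diag((1 - a) * mean(diag(G)), nrow(G)),
                       kind = "GxE", axis_ids = geno$line_ids, check = FALSE)
  ph_gxe <- simulate_phenotypes(geno, list(additive = G,
                                           epistatic = epistasis_kernel(G),
                                           dominance = if (cfg$var_dominance > 0)
                                             dominance_kernel(geno),
                                           gxe = Kge),
                                cfg, trait = "trait_gxe",
                                seed = cfg$seed + 3L)
  phen <- dplyr::left_join(ph_add$phenotypes, ph_gxe$phenotypes,
                           by = c("line", "env", "rep"))
  structure(list(genotypes = geno,
                 transcriptome = trans,
                 abundances = pool_abundances(trans),
                 phenotypes = phen,
                 true_effects = list(trait_additive = ph_add$true_effects,
                                     trait_gxe = ph_gxe$true_effects),
                 config = cfg),
            class = "sim_panel")
}

#' @exportS3Method base::print
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d lines, %d markers, %d genes, %d env(s), %d obs\n",
              nrow(x$genotypes$codes), ncol(x$genotypes$codes),
              ncol(x$abundances), x$config$n_envs, nrow(x$phenotypes)))
  invisible(x)
}
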