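#' The thirteen published model scenarios
#'
#' Catalog of the model formulas compared in the analysis: nine GBLUP
#' scenarios built from separate linear kernels (additive G, epistatic G#G,
#' dominance A, transcriptome T, multi-environment G x E) and four RKHS
#' scenarios where a single Gaussian kernel `G*` on the SNP profiles absorbs
#' additive and cryptic nonadditive genomic effects.
#'
#' @return Character vector of the 13 scenario ids.
#' @export
scenario_ids <- function() names(.scenario_terms)

.scenario_terms <- list(
  G             = c("G"),
  G_EPI         = c("G", "EPI"),
  G_EPI_A       = c("G", "EPI", "A"),
  G_GE          = c("G", "GxE"),
  G_GE_EPI      = c("G", "GxE", "EPI"),
  G_T           = c("G", "T"),
  G_T_EPI       = c("G", "T", "EPI"),
  G_T_GE_EPI    = c("G", "T", "GxE", "EPI"),
  G_T_GE_EPI_A  = c("G", "T", "GxE", "EPI", "A"),
  RKHS_G        = c("GAUSS"),
  RKHS_T        = c("T"),
  RKHS_G_T      = c("GAUSS", "T"),
  RKHS_G_T_GE   = c("GAUSS", "T", "GxE*")
)

#' Term composition of each scenario
#' @return Tibble with `scenario` and its ordered `terms` (list-column).
#' @export
scenario_catalog <- function() {
  tibble::tibble(scenario = names(.scenario_terms),
                 terms = unname(.scenario_terms))
}

#' Bundle the inputs of a prediction analysis
#'
#' Reconciles genotypes, phenotype observations and (optionally) transcript
#' abundances: phenotype rows whose line is absent from the genotype panel
#' are dropped with a message, and abundance rows are aligned to the panel's
#' line order.
#'
#' @param genotypes A [genotype_panel()].
#' @param phenotypes Tibble/data.frame with columns `line`, `env` (optional)
#'   and one column per trait.
#' @param abundances Optional transcript abundances: a lines x genes matrix
#'   (rownames are line ids), a named list of such matrices (one per
#'   environment, names matching the phenotype `env` labels), or a
#'   `sim_transcriptome`. With per-environment abundances the transcriptome
#'   kernel is built at observation level, so T carries environment-specific
#'   expression signal (how the endophenotype captures G x E); with a single
#'   matrix T is a line-level kernel.
#' @return List of class `prediction_bundle`.
#' @export
prediction_bundle <- function(genotypes, phenotypes, abundances = NULL) {
  stopifnot(inherits(genotypes, "genotype_panel"))
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!"line" %in% names(phenotypes)) abort("phenotypes need a 'line' column")
  known <- phenotypes$line %in% genotypes$line_ids
  if (!any(known)) abort("no phenotype line overlaps the genotype panel")
  if (any(!known)) {
    inform(sprintf("dropping %d phenotype row(s) for %d line(s) absent from the genotypes",
                   sum(!known), length(unique(phenotypes$line[!known]))))
    phenotypes <- phenotypes[known, , drop = FALSE]
  }
  envs <- if ("env" %in% names(phenotypes)) {
    unique(as.character(phenotypes$env))
  } else "all"
  if (!is.null(abundances)) {
    if (inherits(abundances, "sim_transcriptome")) {
      abundances <- abundances$abundances
    }
    check_ab <- function(m) {
      m <- as.matrix(m)
      if (is.null(rownames(m))) {
        if (nrow(m) != length(genotypes$line_ids)) {
          abort("unnamed abundance rows do not match the genotype panel")
        }
        rownames(m) <- genotypes$line_ids
      }
      missing_ab <- setdiff(unique(phenotypes$line), rownames(m))
      if (length(missing_ab) > 0) {
        abort(paste0("abundances missing for line(s): ",
                     paste(head(missing_ab, 5), collapse = ", ")))
      }
      m
    }
    if (is.list(abundances) && !is.data.frame(abundances)) {
      if (!all(envs %in% names(abundances))) {
        # environments without their own matrix fall back to the pooled one
        abundances <- check_ab(pool_abundances(abundances))
      } else {
        abundances <- lapply(abundances[envs], check_ab)
      }
    } else {
      abundances <- check_ab(abundances)
    }
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 abundances = abundances, envs = envs),
            class = "prediction_bundle")
}

#' Precompute the kernel set a bundle can support
#'
#' Builds each line-level kernel at most once (G, G#G, A, T, Gaussian G*) and
#' the observation-level G x E expansions, so scenario assembly is cheap.
#' Dominance is skipped with a warning when the panel carries no
#' heterozygous calls (fully inbred material).
#'
#' @param bundle A [prediction_bundle()].
#' @param bandwidth Gaussian bandwidth `h` (`NULL`: median heuristic).
#' @return Named list of kernels (`G`, `EPI`, `A` or `NULL`, `T` or `NULL`,
#'   `GAUSS`, plus observation-level `GxE`, `GxE*` and the incidence
#'   matrices).
#' @export
kernel_set <- function(bundle, bandwidth = NULL) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  geno <- bundle$genotypes
  G <- grm_linear(geno)
  EPI <- epistasis_kernel(G)
  A <- tryCatch(dominance_kernel(geno),
                omicblup_no_heterozygotes = function(e) {
                  warn("fully inbred panel: dominance kernel skipped",
                       class = "omicblup_dominance_skipped")
                  NULL
                })
  W <- suppressWarnings(center_genotypes(geno))
  GAUSS <- gaussian_kernel(W, h = bandwidth)
  phen <- bundle$phenotypes
  obs_ids <- sprintf("obs%05d", seq_len(nrow(phen)))
  ab <- bundle$abundances
  Tk <- NULL
  if (!is.null(ab)) {
    if (is.list(ab) && !is.data.frame(ab)) {
      # per-environment abundances: observation-level transcriptome kernel
      M <- do.call(rbind, lapply(seq_len(nrow(phen)), function(i) {
        ab[[as.character(phen$env[i])]][as.character(phen$line[i]), ,
                                        drop = FALSE]
      }))
      rownames(M) <- obs_ids
      Tk <- transcriptome_kernel(M)
    } else {
      Tk <- transcriptome_kernel(ab)
    }
  }
  Zg <- incidence_matrix(setNames(as.character(phen$line), obs_ids),
                         levels = geno$line_ids)
  ks <- list(G = G, EPI = EPI, A = A, T = Tk, GAUSS = GAUSS, Zg = Zg)
  if (length(bundle$envs) > 1) {
    Ze <- incidence_matrix(setNames(as.character(phen$env), obs_ids),
                           levels = bundle$envs)
    ks$Ze <- Ze
    ks$GxE <- gxe_block_kernel(G, Zg, Ze)
    ks$`GxE*` <- gxe_block_kernel(GAUSS, Zg, Ze)
  }
  ks
}

#' Assemble one scenario as a fittable model
#'
#' Maps a scenario id to its exact term list and binds each term to the
#' bundle's kernels. Transcriptome scenarios require abundances; G x E
#' scenarios require at least two environments. For scenarios with a
#' dominance term on a fully inbred panel the A term is dropped with a
#' warning rather than failing the scenario.
#'
#' @param id One of [scenario_ids()].
#' @param bundle A [prediction_bundle()].
#' @param kernels Optional precomputed [kernel_set()] (built on demand).
#' @param bandwidth Gaussian bandwidth passed to [kernel_set()].
#' @param prior_df,prior_shares Passed to [model_spec()].
#' @return A [model_spec()].
#' @export
build_scenario <- function(id, bundle, kernels = NULL, bandwidth = NULL,
                           prior_df = 5, prior_shares = NULL) {
  if (!id %in% names(.scenario_terms)) {
    abort(paste0("unknown scenario '", id, "'; valid ids: ",
                 paste(names(.scenario_terms), collapse = ", ")))
  }
  stopifnot(inherits(bundle, "prediction_bundle"))
  wanted <- .scenario_terms[[id]]
  if ("T" %in% wanted && is.null(bundle$abundances)) {
    abort(sprintf("scenario %s needs transcript abundances", id))
  }
  if (any(c("GxE", "GxE*") %in% wanted) && length(bundle$envs) < 2) {
    abort(sprintf("scenario %s needs at least two environments", id))
  }
  ks <- kernels %||% kernel_set(bundle, bandwidth = bandwidth)
  if ("A" %in% wanted && is.null(ks$A)) {
    warn(sprintf("scenario %s: dominance term dropped (no heterozygotes)", id),
         class = "omicblup_dominance_skipped")
    wanted <- setdiff(wanted, "A")
  }
  genetic_kinds <- c("G", "EPI", "A", "GAUSS")
  terms <- lapply(wanted, function(w) {
    K <- ks[[w]]
    if (is.null(K)) abort(sprintf("kernel '%s' unavailable in this bundle", w))
    re_term(w, K, incidence = NULL, genetic = w %in% genetic_kinds)
  })
  model_spec(terms, obs = bundle$phenotypes, prior_df = prior_df,
             prior_shares = prior_shares)
}

#' Cross-validate every scenario of the catalog
#'
#' Runs stratified fivefold cross-validation for each requested scenario and
#' trait, collecting mean and standard deviation of the Pearson accuracies
#' in a table shaped like the published scenario-by-trait comparisons.
#' Per-scenario failures are recorded in the `note` column without aborting
#' the remaining scenarios; G x E scenarios are skipped (with the reason)
#' when the bundle has a single environment.
#'
#' @param bundle A [prediction_bundle()].
#' @param traits Trait column names (default: every non-id column of the
#'   phenotype table).
#' @param scenarios Scenario ids or `"all"`.
#' @param plan Optional [make_folds()] plan (built from `seed` otherwise).
#' @param seed Seed for fold assignment and the chains.
#' @param bandwidth Gaussian bandwidth (`NULL`: median heuristic).
#' @param iterations,burn_in,thin Chain settings per fold fit.
#' @return Tibble: `scenario`, `trait`, `mean_r`, `std_r`, `note`, and the
#'   full `cv` report (list-column).
#' @export
run_catalog <- function(bundle, traits = NULL, scenarios = "all",
                        plan = NULL, seed = 1L, bandwidth = NULL,
                        iterations = 3000, burn_in = 1000, thin = 2) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  if (identical(scenarios, "all")) scenarios <- scenario_ids()
  traits <- traits %||% setdiff(names(bundle$phenotypes),
                                c("line", "env", "rep"))
  plan <- plan %||% make_folds(bundle$genotypes$line_ids, seed = seed)
  ks <- kernel_set(bundle, bandwidth = bandwidth)
  grid <- tidyr::expand_grid(scenario = scenarios, trait = traits)
  res <- purrr::pmap(grid, function(scenario, trait) {
    out <- tryCatch({
      model <- build_scenario(scenario, bundle, kernels = ks)
      cv <- crossvalidate(model, bundle, trait = trait, plan = plan,
                          seed = seed, iterations = iterations,
                          burn_in = burn_in, thin = thin)
      list(mean_r = attr(cv, "mean_r"), std_r = attr(cv, "std_r"),
           note = NA_character_, cv = cv)
    }, error = function(e) {
      list(mean_r = NA_real_, std_r = NA_real_,
           note = conditionMessage(e), cv = NULL)
    })
    out
  })
  grid$mean_r <- vapply(res, `[[`, numeric(1), "mean_r")
  grid$std_r <- vapply(res, `[[`, numeric(1), "std_r")
  grid$note <- vapply(res, `[[`, character(1), "note")
  grid$cv <- lapply(res, `[[`, "cv")
  grid
}
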