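#' Read a genotype panel from delimited text or VCF
#'
#' Delimited format: tab-separated with a header row, lines as rows, first
#' column `line`, remaining columns one marker each (codes in `{0,1,2}` or
#' `{-1,0,1}`). VCF: samples become lines and the GT field is summed to an
#' alternate-allele dosage; phased (`|`) and unphased (`/`) separators are
#' treated identically. Multi-allelic VCF records are skipped with a warning
#' (an error in strict mode). Duplicated line ids are an error either way.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param strict Promote recoverable warnings to errors.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf"),
                           strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  }
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    rownames(codes) <- ids
    return(genotype_panel(codes))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    msg <- sprintf("%d multi-allelic record(s) skipped", sum(multi))
    if (strict) abort(paste0("strict mode: ", msg))
    warn(msg, class = "omicblup_multiallelic_skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(multi)) gt <- gt[!multi, , drop = FALSE]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  codes <- t(dose) # lines x markers
  genotype_panel(codes)
}

#' Write a genotype panel
#'
#' `tsv`: the package's tab-separated layout (lines as rows, `line` first
#' column). `vcf`: an uncompressed VCFv4.2 file with synthetic contig and
#' positions (coordinates play no role in kernel construction; only GT
#' identity matters) and codes emitted as unphased diploid genotypes.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "genotype_panel"))
  if (format == "tsv") {
    tab <- tibble::as_tibble(panel$codes, rownames = "line")
    readr::write_tsv(tab, path)
    return(invisible(path))
  }
  m <- ncol(panel$codes)
  gt_map <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- matrix(gt_map[as.character(round(panel$codes))],
               nrow = nrow(panel$codes))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chrS,length=100000000>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$line_ids), collapse = "\t"))
  body <- vapply(seq_len(m), function(k) {
    paste(c("chrS", k, colnames(panel$codes)[k], "A", "B", ".", "PASS", ".",
            "GT", gt[, k]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read transcript abundances (lines x genes, tab-separated)
#' @param path File path; first column `line`, one column per gene.
#' @return Numeric matrix with line ids as row names.
#' @export
read_abundances <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Write transcript abundances
#' @param abundances lines x genes matrix.
#' @param path Output path.
#' @export
write_abundances <- function(abundances, path) {
  readr::write_tsv(tibble::as_tibble(abundances, rownames = "line"), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects tab-separated columns `line`, `env` (optional) and one column per
#' trait. When a genotype panel is supplied, rows for unknown lines are
#' dropped with a reconciliation message (real panels vary slightly in which
#' lines were phenotyped).
#'
#' @param path File path.
#' @param genotypes Optional [genotype_panel()] to reconcile against.
#' @return Tibble of observations.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"line" %in% names(tab)) abort("phenotype file needs a 'line' column")
  tab$line <- as.character(tab$line)
  if (!is.null(genotypes)) {
    known <- tab$line %in% genotypes$line_ids
    if (!any(known)) abort("no phenotype line overlaps the genotype panel")
    if (any(!known)) {
      inform(sprintf("dropped %d phenotype row(s) with unknown line ids",
                     sum(!known)))
      tab <- tab[known, , drop = FALSE]
    }
  }
  tab
}

#' Write a phenotype table
#' @param phenotypes Observation tibble.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(tibble::as_tibble(phenotypes), path)
  invisible(path)
}

#' Write / read a kernel matrix as delimited text
#'
#' Square tab-separated matrix with a header row of axis ids and the ids
#' repeated in the first column.
#'
#' @param K A `kernel_matrix`.
#' @param path File path.
#' @return `write_kernel`: `path` invisibly; `read_kernel`: a
#'   `kernel_matrix`.
#' @export
write_kernel <- function(K, path) {
  tab <- tibble::as_tibble(unclass(K), rownames = "id")
  attr(tab, "kind") <- NULL
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_kernel
#' @param kind Provenance tag to stamp on the re-read kernel.
#' @export
read_kernel <- function(path, kind = "I") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  kernel_matrix(m, kind = kind)
}

#' Write a simulated panel to a directory
#'
#' Emits the full external representation of a [simulate_panel()] result:
#' `genotypes.tsv` and `genotypes.vcf`, one abundance matrix per environment
#' plus the pooled matrix, the phenotype table, and `truth.json` holding the
#' generative variance components and effect vectors for recovery tests.
#'
#' @param panel A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sim_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(panel$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes(panel$genotypes, file.path(dir, "genotypes.vcf"),
                  format = "vcf")
  for (e in names(panel$transcriptome$abundances)) {
    write_abundances(panel$transcriptome$abundances[[e]],
                     file.path(dir, paste0("abundances_", e, ".tsv")))
  }
  write_abundances(panel$abundances, file.path(dir, "abundances_pooled.tsv"))
  write_phenotypes(panel$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- list(
    config = unclass(panel$config),
    trait_additive = lapply(panel$true_effects$trait_additive["variances"],
                            as.list),
    trait_gxe = lapply(panel$true_effects$trait_gxe["variances"], as.list),
    effects = lapply(panel$true_effects, function(te) {
      c(lapply(te$terms, as.numeric),
        list(gxe = lapply(te$gxe, as.numeric),
             intercepts = as.list(te$intercepts)))
    })
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the end-to-end prediction pipeline
#'
#' Single entry point covering simulate -> kernels -> cross-validated
#' scenario catalog -> report. Configuration is a named list or a YAML file
#' with the fields: either `simulate` (a list of [sim_config()] arguments)
#' or input paths `genotypes`, `phenotypes`, `abundances`; plus optional
#' `scenarios` (ids or `"all"`), `traits`, `seed`, `iterations`, `burn_in`,
#' `thin`, `bandwidth`, `strict`, `replicate_analyses` (analyse repeated
#' trait measurement columns `<trait>_1 ... <trait>_k` independently and
#' report their mean accuracy as `<trait>`), and `out` (output directory). Outputs: the kernel
#' matrices, the scenario report (`cv_report.tsv`, scenario rows with
#' `mean (std)` columns per trait), and a `manifest.yaml` recording seeds,
#' chain settings, package version and realised defaults so a rerun
#' reproduces every number.
#'
#' @param config Named list or path to a YAML file.
#' @param out Output directory (overrides `config$out`).
#' @return The report tibble, invisibly; files under the output directory.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- out %||% config$out %||% abort("config needs an output directory 'out'")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  scen <- config$scenarios %||% "all"
  if (length(scen) == 1 && scen != "all") {
    scen <- strsplit(scen, ",")[[1]]
  }
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, modifyList(config$simulate,
                                          list(seed = seed)))
    sp <- simulate_panel(cfg)
    write_sim_panel(sp, file.path(out, "simulated"))
    geno <- sp$genotypes
    phen <- sp$phenotypes
    ab <- sp$transcriptome
  } else {
    for (f in c("genotypes", "phenotypes")) {
      if (is.null(config[[f]])) abort(sprintf("config needs '%s'", f))
      if (!file.exists(config[[f]])) {
        abort(sprintf("input path does not exist: %s", config[[f]]))
      }
    }
    geno <- read_genotypes(config$genotypes, strict = isTRUE(config$strict))
    phen <- read_phenotypes(config$phenotypes, genotypes = geno)
    ab <- NULL
    if (!is.null(config$abundances)) {
      if (!file.exists(config$abundances)) {
        abort(sprintf("input path does not exist: %s", config$abundances))
      }
      ab <- read_abundances(config$abundances)
    }
  }
  if (is.null(ab) && !identical(scen, "all")) {
    t_scen <- scen[vapply(scen, function(s)
      "T" %in% (.scenario_terms[[s]] %||% character(0)), logical(1))]
    if (length(t_scen) > 0) {
      abort(paste0("transcriptome scenario(s) requested without abundances: ",
                   paste(t_scen, collapse = ", ")))
    }
  }
  bundle <- prediction_bundle(geno, phen, abundances = ab)
  ks <- kernel_set(bundle, bandwidth = config$bandwidth)
  kdir <- file.path(out, "kernels")
  dir.create(kdir, showWarnings = FALSE)
  for (nm in c("G", "EPI", "A", "T", "GAUSS")) {
    if (!is.null(ks[[nm]])) {
      write_kernel(ks[[nm]], file.path(kdir, paste0(nm, ".tsv")))
    }
  }
  report <- run_catalog(bundle, traits = config$traits,
                        scenarios = scen, seed = seed,
                        bandwidth = config$bandwidth,
                        iterations = config$iterations %||% 3000,
                        burn_in = config$burn_in %||% 1000,
                        thin = config$thin %||% 2)
  if (isTRUE(config$replicate_analyses)) {
    # repeated trait measurements (columns <trait>_1, <trait>_2, ...) are
    # analysed independently; their mean accuracy is reported as <trait>
    rep_rows <- report |>
      dplyr::mutate(base = sub("_[0-9]+$", "", .data$trait)) |>
      dplyr::filter(.data$base != .data$trait) |>
      dplyr::group_by(.data$scenario, .data$base) |>
      dplyr::summarise(mean_r = mean(.data$mean_r),
                       std_r = mean(.data$std_r),
                       note = NA_character_, .groups = "drop") |>
      dplyr::rename(trait = "base")
    rep_rows$cv <- vector("list", nrow(rep_rows))
    report <- dplyr::bind_rows(report, rep_rows)
  }
  wide <- report |>
    dplyr::mutate(cell = sprintf("%.3f (%.3f)", .data$mean_r, .data$std_r)) |>
    dplyr::select("scenario", "trait", "cell") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "cell")
  readr::write_tsv(wide, file.path(out, "cv_report.tsv"))
  readr::write_tsv(dplyr::select(report, -"cv"),
                   file.path(out, "cv_report_long.tsv"))
  manifest <- list(
    package = "omicblup",
    version = as.character(packageVersion("omicblup")),
    seed = seed,
    scenarios = scen,
    chain = list(iterations = config$iterations %||% 3000,
                 burn_in = config$burn_in %||% 1000,
                 thin = config$thin %||% 2),
    bandwidth = attr(ks$GAUSS, "bandwidth"),
    n_lines = length(geno$line_ids),
    n_markers = ncol(geno$codes),
    n_obs = nrow(phen)
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(report)
}

#' Persist posterior draws of a fit as delimited text
#'
#' Writes `draws.tsv` (one row per retained draw: variance components and
#' intercepts), `effects.tsv` (posterior-mean effect vectors per term and
#' the fitted linear predictor), and `run_metadata.yaml` (chain settings,
#' seed, realised hyperpriors, effective sample sizes) so a run can be
#' archived and reproduced exactly.
#'
#' @param fit A `kernel_gibbs` fit.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "kernel_gibbs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draws <- tibble::as_tibble(cbind(fit$variance_draws,
                                   fit$intercept_draws), .name_repair = "minimal")
  names(draws) <- c(paste0("sigma2_", colnames(fit$variance_draws)),
                    paste0("mu_", colnames(fit$intercept_draws)))
  readr::write_tsv(draws, file.path(dir, "draws.tsv"))
  eff <- tibble::as_tibble(fit$model$obs[, intersect(c("line", "env"),
                                                     names(fit$model$obs))])
  for (nm in names(fit$effect_means)) eff[[nm]] <- fit$effect_means[[nm]]
  eff$.fitted <- fit$fitted_mean
  readr::write_tsv(eff, file.path(dir, "effects.tsv"))
  yaml::write_yaml(list(
    chain = fit$chain,
    hyperpriors = list(df = fit$hyperpriors$df,
                       scale_u = as.list(setNames(as.numeric(fit$hyperpriors$scale_u),
                                                  names(fit$effect_means))),
                       scale_e = fit$hyperpriors$scale_e),
    ess = as.list(setNames(as.numeric(fit$ess), names(fit$ess))),
    n_obs = fit$model$n,
    n_masked = length(fit$missing)
  ), file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
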