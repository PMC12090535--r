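#' Partition lines into cross-validation folds
#'
#' Random near-equal partition of the lines into `k` folds (sizes differing
#' by at most one). Folding is by line, not by observation: all of a line's
#' observations across environments and replicates share a fold, so a
#' genotype is never simultaneously in training and test.
#'
#' @param line_ids Character vector of line ids (at least `k`).
#' @param k Number of folds (default 5).
#' @param seed RNG seed making the assignment deterministic.
#' @return Tibble `line`, `fold` of class `fold_plan` with a `seed`
#'   attribute.
#' @export
#' @examples
#' table(make_folds(sprintf("L%03d", 1:286), seed = 1)$fold)
make_folds <- function(line_ids, k = 5, seed = 1L) {
  line_ids <- as.character(line_ids)
  if (length(line_ids) < k) {
    abort(sprintf("need at least %d lines for %d folds", k, k))
  }
  set.seed(seed)
  shuffled <- sample(line_ids)
  fold <- rep(seq_len(k), length.out = length(line_ids))
  # rep() cycles 1..k so fold sizes differ by <= 1; order by shuffle
  plan <- tibble::tibble(line = shuffled, fold = fold) |>
    dplyr::arrange(match(.data$line, line_ids))
  structure(plan, class = c("fold_plan", class(plan)), seed = seed)
}

#' Pearson correlation between observed and predicted values
#'
#' Plain product-moment correlation used as the predictive-accuracy score.
#' Requires at least three complete pairs and nonzero variance on both
#' sides; otherwise the score is undefined and returned as `NA` with a
#' warning.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Scalar `r` in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(y_true, y_pred) {
  ok <- is.finite(y_true) & is.finite(y_pred)
  if (sum(ok) < 3) {
    warn("fewer than 3 complete pairs: correlation undefined",
         class = "omicblup_r_undefined")
    return(NA_real_)
  }
  if (sd(y_true[ok]) == 0 || sd(y_pred[ok]) == 0) {
    warn("zero variance: correlation undefined",
         class = "omicblup_r_undefined")
    return(NA_real_)
  }
  cor(y_true[ok], y_pred[ok])
}

#' Environment-stratified k-fold cross-validation of one model
#'
#' For each fold, the phenotypes of the held-out lines are masked (`NA`) and
#' the model is refitted on the shared kernels -- whole-kernel train/test
#' conditioning -- then the masked observations are predicted. Accuracy is
#' scored within each environment (Pearson r between observed and predicted
#' values of the held-out lines) and averaged across environments to give
#' the fold-level accuracy; the report's mean and standard deviation are
#' taken across the fold-level values. A pooled (non-stratified) r per fold
#' is also kept for diagnostics.
#'
#' @param model A [model_spec()] built on the bundle's full observation
#'   table, or a scenario id (then `bundle` is used to build it).
#' @param bundle A [prediction_bundle()].
#' @param trait Trait column of the bundle's phenotype table.
#' @param plan A [make_folds()] plan covering the bundle's lines.
#' @param seed Chain seed (fold index is added so folds get distinct
#'   chains).
#' @param iterations,burn_in,thin Chain settings.
#' @param ess_warn Effective-sample-size warning threshold forwarded to
#'   [gibbs_fit()]; 0 by default here because the report averages posterior
#'   mean predictions over folds and slow variance mixing in a short
#'   per-fold chain is expected.
#' @param ... Passed to [gibbs_fit()].
#' @return Tibble of class `cv_report` (`fold`, `env`, `r`, `n_test`) with
#'   attributes `mean_r`, `std_r`, `pooled_r`, `trait`, `scenario`, and
#'   `predictions` (a tibble of held-out observations with their `.pred`).
#' @export
crossvalidate <- function(model, bundle, trait, plan = NULL, seed = 1L,
                          iterations = 3000, burn_in = 1000, thin = 2,
                          ess_warn = 0, ...) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  scenario <- NA_character_
  if (is.character(model)) {
    scenario <- model
    model <- build_scenario(model, bundle)
  }
  stopifnot(inherits(model, "model_spec"))
  phen <- bundle$phenotypes
  if (!trait %in% names(phen)) {
    abort(sprintf("trait '%s' not found in the phenotype table", trait))
  }
  plan <- plan %||% make_folds(bundle$genotypes$line_ids, seed = seed)
  missing_lines <- setdiff(unique(phen$line), plan$line)
  if (length(missing_lines) > 0) {
    abort(paste0("fold plan does not cover line(s): ",
                 paste(head(missing_lines, 5), collapse = ", ")))
  }
  y_all <- phen[[trait]]
  fold_of <- plan$fold[match(phen$line, plan$line)]
  envs <- if ("env" %in% names(phen)) as.character(phen$env)
          else rep("all", nrow(phen))
  folds <- sort(unique(plan$fold))
  rows <- list()
  preds <- list()
  pooled <- numeric(0)
  fold_means <- numeric(0)
  for (f in folds) {
    test <- fold_of == f & !is.na(y_all)
    y_mask <- y_all
    y_mask[fold_of == f] <- NA
    if (all(is.na(y_mask))) next
    fit <- gibbs_fit(y_mask, model, iterations = iterations,
                     burn_in = burn_in, thin = thin, seed = seed + f,
                     ess_warn = ess_warn, ...)
    pred <- fit$fitted_mean
    preds[[length(preds) + 1L]] <- tibble::tibble(
      fold = f, line = as.character(phen$line[test]), env = envs[test],
      observed = y_all[test], .pred = pred[test])
    rs <- c()
    for (e in unique(envs)) {
      sel <- test & envs == e
      r_e <- if (sum(sel) >= 3) {
        suppressWarnings(pearson_r(y_all[sel], pred[sel]))
      } else NA_real_
      if (is.na(r_e)) {
        warn(sprintf("fold %d, environment %s: accuracy undefined; cell excluded",
                     f, e), class = "omicblup_cv_cell_missing")
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(fold = f, env = e, r = r_e, n_test = sum(sel))
      rs <- c(rs, r_e)
    }
    fold_means <- c(fold_means, mean(rs, na.rm = TRUE))
    pooled <- c(pooled, suppressWarnings(pearson_r(y_all[test], pred[test])))
  }
  rep_tbl <- dplyr::bind_rows(rows)
  structure(rep_tbl,
            class = c("cv_report", class(rep_tbl)),
            mean_r = mean(fold_means, na.rm = TRUE),
            std_r = sd(fold_means, na.rm = TRUE),
            pooled_r = mean(pooled, na.rm = TRUE),
            fold_means = fold_means,
            predictions = dplyr::bind_rows(preds),
            trait = trait, scenario = scenario)
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report%s trait=%s> mean r = %.3f (sd %.3f), pooled r = %.3f\n",
              if (!is.na(attr(x, "scenario"))) paste0(" ", attr(x, "scenario")) else "",
              attr(x, "trait"), attr(x, "mean_r"), attr(x, "std_r"),
              attr(x, "pooled_r")))
  NextMethod()
  invisible(x)
}

#' Tidy per-fold accuracies of a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("fold", "env", "r", "n_test")])
}

#' One-row summary of a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(trait = attr(x, "trait"), scenario = attr(x, "scenario"),
                 mean_r = attr(x, "mean_r"), std_r = attr(x, "std_r"),
                 pooled_r = attr(x, "pooled_r"),
                 folds = length(attr(x, "fold_means")))
}
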