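#' Eigen-decompose a kernel for the diagonalised sampler
#'
#' Factorises a symmetric PSD kernel as `K = U Lambda U'`. Eigenvalues below
#' zero (float noise) are clipped; eigenvalues below `rank_tol * lambda_max`
#' are truncated away so the sampler works in the kernel's numerical rank.
#' Under the transformation `s = U' u` the effect prior becomes independent
#' Gaussian, `s ~ N(0, Lambda sigma_u^2)`, and the working response
#' `t = U' y` has iid residuals -- so every full conditional in the sampler
#' is diagonal.
#'
#' @param K Symmetric matrix (class `kernel_matrix` or plain).
#' @param rank_tol Relative truncation threshold (default `1e-10`).
#' @return List of class `eigen_kernel`: `vectors` (n x r), `values`
#'   (length r, positive), `rank`, `n`.
#' @export
eigendecompose <- function(K, rank_tol = 1e-10) {
  M <- unclass(K)
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6 * max(abs(M), 1e-12)) {
    abort(sprintf("matrix is asymmetric beyond tolerance (%.3g)", asym))
  }
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  lmax <- max(ev$values, 0)
  vals <- pmax(ev$values, 0)
  keep <- vals > rank_tol * max(lmax, 1e-300)
  if (!any(keep)) abort("kernel has numerical rank zero")
  structure(list(vectors = ev$vectors[, keep, drop = FALSE],
                 values = vals[keep],
                 rank = sum(keep),
                 n = nrow(M)),
            class = "eigen_kernel")
}

#' Define one kernel random-effect term
#'
#' @param name Term label (e.g. `"G"`, `"EPI"`, `"T"`, `"GxE"`).
#' @param kernel `kernel_matrix`, at line level (then `incidence` maps
#'   observations to lines) or already at observation level.
#' @param incidence Optional [incidence_matrix()] (observations x lines);
#'   `NULL` means the kernel is already observation-level (or one
#'   observation per line).
#' @param genetic Is this a genetic main effect contributing to GEBVs?
#'   (G, G#G, A and Gaussian G* terms are; T and G x E are not.)
#' @return List of class `re_term`.
#' @export
re_term <- function(name, kernel, incidence = NULL, genetic = FALSE) {
  structure(list(name = name, kernel = kernel, incidence = incidence,
                 genetic = genetic),
            class = "re_term")
}

#' Specify a multi-kernel mixed model
#'
#' An intercept structure plus an ordered list of kernel random-effect terms
#' and a residual, each variance carrying a scaled inverse chi-squared prior.
#' When `env` is supplied (more than one level) the intercept is fitted per
#' environment; otherwise a single intercept is used.
#'
#' @param terms List of [re_term()]s (at least one).
#' @param obs Tibble/data.frame of observations with a `line` column and
#'   (optionally) `env`; defines the observation order shared by `y`.
#' @param prior_df Degrees of freedom of every scaled-inv-chi^2 variance
#'   prior (default 5, the BGLR convention).
#' @param prior_shares Optional named/numeric vector of prior variance shares
#'   for the terms plus residual (default: equal split); prior scales are set
#'   so each prior mode equals its share of the phenotypic variance.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(terms, obs, prior_df = 5, prior_shares = NULL) {
  if (inherits(terms, "re_term")) terms <- list(terms)
  if (length(terms) < 1) abort("model needs at least one random-effect term")
  if (!all(vapply(terms, inherits, logical(1), "re_term"))) {
    abort("terms must be re_term objects")
  }
  obs <- tibble::as_tibble(obs)
  if (!"line" %in% names(obs)) abort("obs must have a 'line' column")
  n <- nrow(obs)
  env <- if ("env" %in% names(obs)) factor(obs$env) else factor(rep("all", n))
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  # resolve every term to an observation-level kernel
  Kobs <- lapply(terms, function(tm) {
    K <- tm$kernel
    if (!is.null(tm$incidence)) {
      Z <- tm$incidence
      if (ncol(Z) != nrow(K)) abort(sprintf(
        "term '%s': incidence columns (%d) do not match kernel axis (%d)",
        tm$name, ncol(Z), nrow(K)))
      K <- Z %*% unclass(K) %*% t(Z)
    } else if (!is.null(rownames(K)) &&
               all(as.character(obs$line) %in% rownames(K))) {
      # line-level kernel: expand through the line ids
      idx <- match(as.character(obs$line), rownames(K))
      if (anyNA(idx)) {
        abort(sprintf("term '%s': line(s) absent from kernel axis: %s",
                      tm$name,
                      paste(head(unique(obs$line[is.na(idx)]), 5),
                            collapse = ", ")))
      }
      K <- unclass(K)[idx, idx]
    } else if (nrow(K) != n) {
      abort(sprintf(
        "term '%s': kernel (%d) matches neither the observations (%d) nor the line ids",
        tm$name, nrow(K), n))
    }
    unclass(K)
  })
  q <- length(terms)
  shares <- prior_shares %||% rep(1 / (q + 1), q + 1)
  if (length(shares) != q + 1) abort("prior_shares must have length terms+1")
  structure(list(terms = terms, K_obs = Kobs, obs = obs, env = env,
                 intercept_mode = if (nlevels(env) > 1) "per_env" else "single",
                 prior_df = prior_df, prior_shares = shares, n = n),
            class = "model_spec")
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d obs, intercept: %s\n  terms: %s\n", x$n,
              x$intercept_mode, paste(names(x$terms), collapse = " + ")))
  invisible(x)
}

scaled_inv_chisq_draw <- function(ss, n_eff, df, S, floor = 1e-10) {
  max((ss + df * S) / rchisq(1, df + n_eff), floor)
}

#' Fit a multi-kernel model by Gibbs sampling
#'
#' Bayesian hierarchical model: `y = mu + sum_k u_k + e`, with
#' `u_k ~ N(0, sigma_k^2 K_k)`, `e ~ N(0, sigma_e^2 I)`, a flat prior on the
#' intercept(s) and scaled inverse chi-squared priors on all variances. Every
#' full conditional is conjugate, and by default each kernel is
#' eigen-decomposed so the effect updates work on independent transformed
#' coordinates (`method = "eigen"`); `method = "direct"` samples the
#' untransformed multivariate-normal conditionals (slow; kept as an internal
#' cross-check of the transformation).
#'
#' Missing responses are allowed and handled by data augmentation: masked
#' observations are imputed from the current model draw each sweep, which is
#' exactly the whole-kernel train/test conditioning used for
#' cross-validation (test phenotypes masked, kernels shared).
#'
#' @param y Numeric response in `model$obs` order; `NA` marks masked
#'   (to-be-predicted) observations.
#' @param model A [model_spec()].
#' @param iterations,burn_in,thin Chain settings (defaults 12000 / 2000 / 5).
#' @param seed RNG seed for a reproducible chain.
#' @param method `"eigen"` (diagonalised, default) or `"direct"`.
#' @param fix_variances Optional named list/vector fixing selected variance
#'   components (term names, or `"residual"`) at given values instead of
#'   sampling them.
#' @param ess_warn Warn when any variance component's effective sample size
#'   falls below this (default 100).
#' @return Object of class `kernel_gibbs` with posterior draws of variances
#'   and intercepts, posterior means of each effect vector and of the linear
#'   predictor, realised hyperpriors and chain metadata.
#' @export
gibbs_fit <- function(y, model, iterations = 12000, burn_in = 2000,
                      thin = 5, seed = NULL, method = c("eigen", "direct"),
                      fix_variances = NULL, ess_warn = 100) {
  method <- match.arg(method)
  stopifnot(inherits(model, "model_spec"))
  n <- model$n
  if (length(y) != n) abort("length(y) does not match model observations")
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  if (all(is.na(y))) abort("y has no observed values")
  if (any(!is.finite(y[!is.na(y)]))) abort("y contains non-finite values")
  if (!is.null(seed)) set.seed(seed)

  q <- length(model$terms)
  df <- model$prior_df
  vy <- var(y, na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  shares <- model$prior_shares
  mdiag <- vapply(model$K_obs, function(K) mean(diag(K)), numeric(1))
  S_u <- shares[seq_len(q)] * vy * (df + 2) / (df * pmax(mdiag, 1e-12))
  S_e <- shares[q + 1] * vy * (df + 2) / df

  eig <- NULL; Kinv <- NULL
  if (method == "eigen") {
    eig <- lapply(model$K_obs, eigendecompose)
  } else {
    Kinv <- lapply(model$K_obs, function(K) {
      solve(K + diag(1e-8 * mean(diag(K)), n))
    })
  }

  env <- model$env
  env_idx <- split(seq_len(n), env)
  miss <- which(is.na(y))
  yobs <- y
  ycur <- ifelse(is.na(y), mean(y, na.rm = TRUE), y)

  sig2 <- setNames(shares[seq_len(q)] * vy / pmax(mdiag, 1e-12),
                   names(model$terms))
  sig2_e <- shares[q + 1] * vy
  fixed <- rep(FALSE, q); fixed_e <- FALSE
  if (!is.null(fix_variances)) {
    fv <- unlist(fix_variances)
    for (nm in names(fv)) {
      if (nm == "residual") {
        sig2_e <- fv[[nm]]; fixed_e <- TRUE
      } else if (nm %in% names(sig2)) {
        sig2[nm] <- fv[[nm]]; fixed[match(nm, names(sig2))] <- TRUE
      } else {
        abort(sprintf("fix_variances: unknown component '%s'", nm))
      }
    }
  }

  u <- lapply(seq_len(q), function(k) rep(0, n))
  mu <- setNames(vapply(env_idx, function(ix) mean(ycur[ix]), numeric(1)),
                 levels(env))
  n_keep <- floor((iterations - burn_in) / thin)
  vdraws <- matrix(NA_real_, n_keep, q + 1,
                   dimnames = list(NULL, c(names(model$terms), "residual")))
  idraws <- matrix(NA_real_, n_keep, nlevels(env),
                   dimnames = list(NULL, levels(env)))
  u_mean <- lapply(seq_len(q), function(k) rep(0, n))
  eta_mean <- rep(0, n)
  kept <- 0L

  for (it in seq_len(iterations)) {
    # impute masked responses from the current draw
    eta <- mu[as.integer(env)] + Reduce(`+`, u, accumulate = FALSE)
    if (length(miss) > 0) {
      ycur[miss] <- eta[miss] + rnorm(length(miss), sd = sqrt(sig2_e))
    }
    # intercept(s), flat prior
    r0 <- ycur - (eta - mu[as.integer(env)])
    for (j in seq_len(nlevels(env))) {
      ix <- env_idx[[j]]
      mu[j] <- rnorm(1, mean(r0[ix]), sqrt(sig2_e / length(ix)))
    }
    # kernel effects
    for (k in seq_len(q)) {
      r <- ycur - mu[as.integer(env)]
      for (k2 in seq_len(q)) if (k2 != k) r <- r - u[[k2]]
      if (method == "eigen") {
        E <- eig[[k]]
        tt <- crossprod(E$vectors, r)
        lam <- E$values
        shrink <- lam * sig2[k] / (lam * sig2[k] + sig2_e)
        s <- rnorm(E$rank, mean = shrink * tt,
                   sd = sqrt(shrink * sig2_e))
        u[[k]] <- as.vector(E$vectors %*% s)
        if (!fixed[k]) {
          sig2[k] <- scaled_inv_chisq_draw(sum(s^2 / lam), E$rank, df, S_u[k])
        }
      } else {
        C <- diag(1 / sig2_e, n) + Kinv[[k]] / sig2[k]
        R <- chol(C)
        mean_u <- backsolve(R, forwardsolve(t(R), r / sig2_e))
        u[[k]] <- as.vector(mean_u + backsolve(R, rnorm(n)))
        if (!fixed[k]) {
          ss <- as.numeric(crossprod(u[[k]], Kinv[[k]] %*% u[[k]]))
          sig2[k] <- scaled_inv_chisq_draw(ss, n, df, S_u[k])
        }
      }
    }
    # residual variance
    e <- ycur - mu[as.integer(env)] - Reduce(`+`, u)
    if (!fixed_e) {
      sig2_e <- scaled_inv_chisq_draw(sum(e^2), n, df, S_e)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      vdraws[kept, ] <- c(sig2, sig2_e)
      idraws[kept, ] <- mu
      for (k in seq_len(q)) u_mean[[k]] <- u_mean[[k]] + u[[k]]
      eta_mean <- eta_mean + mu[as.integer(env)] + Reduce(`+`, u)
    }
  }
  u_mean <- lapply(u_mean, function(v) v / kept)
  eta_mean <- eta_mean / kept
  names(u_mean) <- names(model$terms)
  ess <- apply(vdraws, 2, ess_autocorr)
  if (any(ess < ess_warn)) {
    warn(sprintf("low effective sample size for variance component(s): %s",
                 paste(colnames(vdraws)[ess < ess_warn], collapse = ", ")),
         class = "omicblup_low_ess")
  }
  structure(list(variance_draws = vdraws, intercept_draws = idraws,
                 effect_means = u_mean, fitted_mean = eta_mean,
                 y = yobs, missing = miss, model = model,
                 hyperpriors = list(df = df, scale_u = S_u, scale_e = S_e),
                 chain = list(iterations = iterations, burn_in = burn_in,
                              thin = thin, seed = seed, draws = kept,
                              method = method),
                 ess = ess),
            class = "kernel_gibbs")
}

# effective sample size from the initial positive autocorrelation sequence
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' @exportS3Method base::print
print.kernel_gibbs <- function(x, ...) {
  cat(sprintf("<kernel_gibbs> %d obs (%d masked), %d retained draws (%s)\n",
              x$model$n, length(x$missing), x$chain$draws, x$chain$method))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of the variance components
#'
#' @param x A `kernel_gibbs` fit.
#' @param conf.level Credible-interval mass (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior sd), `conf.low`, `conf.high`, `ess`.
#' @export
tidy.kernel_gibbs <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  d <- x$variance_draws
  tibble::tibble(
    term = colnames(d),
    estimate = colMeans(d),
    std.error = apply(d, 2, sd),
    conf.low = apply(d, 2, quantile, probs = a),
    conf.high = apply(d, 2, quantile, probs = 1 - a),
    ess = as.numeric(x$ess)
  )
}

#' One-row summary of a Gibbs fit
#' @param x A `kernel_gibbs` fit.
#' @param ... Unused.
#' @export
glance.kernel_gibbs <- function(x, ...) {
  tibble::tibble(
    nobs = x$model$n,
    n_masked = length(x$missing),
    n_terms = length(x$model$terms),
    sigma2_residual = mean(x$variance_draws[, "residual"]),
    draws = x$chain$draws,
    min_ess = min(x$ess)
  )
}

#' Posterior predictions for observations
#'
#' Posterior mean of the linear predictor (intercept plus the sum of all
#' random-effect terms) for the requested observations of the fitted design.
#' Under whole-kernel conditioning, predictions for masked observations are
#' the model's out-of-sample predictions; for observed ones they are fitted
#' values.
#'
#' @param object A `kernel_gibbs` fit.
#' @param obs Observation selector: `NULL` (all), integer indices, or a
#'   logical vector.
#' @param ... Unused.
#' @return Tibble: the selected observation rows plus `.pred`.
#' @export
posterior_predict <- function(object, obs = NULL, ...) {
  stopifnot(inherits(object, "kernel_gibbs"))
  idx <- if (is.null(obs)) seq_len(object$model$n)
         else if (is.logical(obs)) which(obs)
         else as.integer(obs)
  out <- object$model$obs[idx, , drop = FALSE]
  out$.pred <- object$fitted_mean[idx]
  tibble::as_tibble(out)
}

#' Genomic estimated breeding values
#'
#' Per-line posterior mean of the genetic random effects -- the terms flagged
#' `genetic = TRUE` (G, G#G, A, and the RKHS G* term). Transcriptome and
#' G x E terms are excluded by default, matching the definition of a breeding
#' value as the summed genetic effects; pass term names to override.
#'
#' @param fit A `kernel_gibbs` fit.
#' @param terms Optional character vector of term names to sum instead of
#'   the genetic flags.
#' @return Tibble `line`, `gebv` (one row per line, observation effects
#'   averaged within line).
#' @export
gebv <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "kernel_gibbs"))
  model <- fit$model
  use <- terms %||%
    names(model$terms)[vapply(model$terms, `[[`, logical(1), "genetic")]
  if (length(use) == 0) {
    abort("model has no genetic term: GEBVs are undefined")
  }
  bad <- setdiff(use, names(model$terms))
  if (length(bad) > 0) abort(paste("unknown term(s):", paste(bad, collapse = ", ")))
  tot <- Reduce(`+`, fit$effect_means[use])
  tibble::tibble(line = as.character(model$obs$line), value = tot) |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(gebv = mean(.data$value), .groups = "drop")
}
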