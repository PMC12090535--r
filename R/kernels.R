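#' Kernel (relationship) matrices
#'
#' All variance-covariance structures used by the prediction models are
#' represented as `kernel_matrix` objects: symmetric positive semi-definite
#' matrices over lines (or observations) carrying a provenance tag. The tag
#' (`kind`) records how the kernel was built: `"G"` additive genomic
#' relationship matrix, `"EPI"` epistatic Hadamard square, `"A"` dominance,
#' `"T"` transcriptome linear kernel, `"GAUSS"` Gaussian RKHS kernel,
#' `"GxE"` environment-blocked expansion, `"I"` identity/custom.
#'
#' @param entries Symmetric numeric matrix.
#' @param kind Provenance tag.
#' @param bandwidth Bandwidth used (Gaussian kernels only).
#' @param axis_ids Ids for rows/columns; defaults to existing dimnames.
#' @param check Validate symmetry and eigenvalue floor (default `TRUE`).
#'
#' @return A matrix of class `kernel_matrix` with attributes `kind` and
#'   (optionally) `bandwidth`.
#' @export
kernel_matrix <- function(entries, kind = "I", bandwidth = NULL,
                          axis_ids = NULL, check = TRUE) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) abort("kernel must be square")
  if (!is.null(axis_ids)) {
    dimnames(entries) <- list(axis_ids, axis_ids)
  } else if (is.null(rownames(entries))) {
    ids <- sprintf("L%03d", seq_len(nrow(entries)))
    dimnames(entries) <- list(ids, ids)
  } else {
    colnames(entries) <- rownames(entries)
  }
  if (anyDuplicated(rownames(entries))) abort("kernel axis ids must be unique")
  if (check) {
    asym <- max(abs(entries - t(entries)))
    scale <- max(abs(entries), 1e-12)
    if (asym > 1e-8 * scale) {
      abort(sprintf("kernel not symmetric (max asymmetry %.3g)", asym))
    }
    entries <- (entries + t(entries)) / 2
  }
  structure(entries, class = c("kernel_matrix", "matrix", "array"),
            kind = kind, bandwidth = bandwidth)
}

#' @exportS3Method base::print
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix kind=%s> %d x %d, mean diag %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

kernel_kind <- function(K) attr(K, "kind") %||% "I"

#' Check (and optionally repair) positive semi-definiteness
#'
#' Eigenvalues below `-tol * lambda_max` indicate a genuinely indefinite
#' matrix and raise an error; small negative eigenvalues inside the tolerance
#' band are float noise (typical after large Hadamard products) and are
#' clipped to zero with a warning when `repair = TRUE`.
#'
#' @param K kernel_matrix or plain symmetric matrix.
#' @param tol Relative eigenvalue floor (default `1e-8`).
#' @param repair Clip in-tolerance negative eigenvalues (default `FALSE`:
#'   check only).
#' @return `K` (possibly repaired), invisibly for pure checks.
#' @export
check_psd <- function(K, tol = 1e-8, repair = FALSE) {
  ev <- eigen(K, symmetric = TRUE, only.values = !repair)
  lmax <- max(ev$values, 0)
  floor_ <- -tol * max(lmax, 1e-12)
  if (min(ev$values) < floor_) {
    abort(sprintf("kernel is not PSD: min eigenvalue %.3g < %.3g",
                  min(ev$values), floor_))
  }
  if (repair && min(ev$values) < 0) {
    warn("clipping small negative eigenvalues to zero",
         class = "omicblup_psd_repair")
    vals <- pmax(ev$values, 0)
    K2 <- ev$vectors %*% (vals * t(ev$vectors))
    K2 <- kernel_matrix(K2, kind = kernel_kind(K),
                        bandwidth = attr(K, "bandwidth"),
                        axis_ids = rownames(K), check = FALSE)
    return(K2)
  }
  invisible(K)
}

#' Additive genomic relationship matrix (linear kernel)
#'
#' VanRaden-style GRM: `G = W W' / (2 * sum_k p_k (1 - p_k))` with `W` the
#' genotype matrix centred by twice the allele frequency. The scaling makes
#' the mean diagonal equal `1 + f`, `f` the panel's inbreeding coefficient.
#'
#' @param panel A [genotype_panel()] with at least two polymorphic markers.
#' @return A `kernel_matrix` with kind `"G"`.
#' @export
#' @examples
#' gp <- genotype_panel(matrix(c(0, 1, 2), ncol = 1,
#'                             dimnames = list(c("a", "b", "c"), "m1")))
#' grm_linear(gp)
grm_linear <- function(panel) {
  W <- suppressWarnings(center_genotypes(panel))
  p <- panel$allele_freq[attr(W, "markers")]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all markers monomorphic: GRM denominator is zero")
  kernel_matrix(tcrossprod(W) / denom, kind = "G")
}

#' Epistatic relationship matrix (Hadamard square of the GRM)
#'
#' Locus-by-locus interaction structure `G # G`: the elementwise (Schur)
#' product of the additive GRM with itself. PSD by the Schur product theorem.
#'
#' @param G The additive `kernel_matrix` from [grm_linear()].
#' @return A `kernel_matrix` with kind `"EPI"`.
#' @export
epistasis_kernel <- function(G) {
  if (nrow(G) != ncol(G)) abort("epistasis kernel needs a square GRM")
  kernel_matrix(unclass(G) * unclass(G), kind = "EPI",
                axis_ids = rownames(G))
}

#' Dominance relationship matrix
#'
#' Within-locus allelic interaction captured by recoding each marker as a
#' homozygosity indicator: 1 for AA or BB, 0 for the heterozygote AB. The
#' indicator matrix is column-centred, cross-multiplied, and rescaled to a
#' mean diagonal of 1 so its variance component is comparable with the other
#' kernels.
#'
#' @param panel A [genotype_panel()] containing at least one heterozygous
#'   call; a fully inbred panel has a constant indicator and raises an error
#'   advising that the dominance term be dropped.
#' @return A `kernel_matrix` with kind `"A"`.
#' @export
dominance_kernel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  # fractional (imputed) codes count as non-homozygous weight
  H <- 1 - pmax(1 - abs(panel$codes - 1), 0)
  if (all(panel$codes != 1)) {
    abort(paste("panel has no heterozygous calls: dominance design is",
                "constant and the dominance term should be dropped"),
          class = "omicblup_no_heterozygotes")
  }
  Hc <- scale(H, center = TRUE, scale = FALSE)
  v <- apply(Hc, 2, function(x) any(x != 0))
  Hc <- Hc[, v, drop = FALSE]
  if (ncol(Hc) == 0) {
    abort("all dominance indicator columns constant; drop the dominance term",
          class = "omicblup_no_heterozygotes")
  }
  A <- tcrossprod(Hc)
  A <- A / mean(diag(A))
  kernel_matrix(A, kind = "A", axis_ids = panel$line_ids)
}

#' Transcriptome linear kernel
#'
#' Linear kernel over normalised transcript abundances: each gene is
#' standardised to mean 0 and unit variance (zero-variance genes dropped with
#' a warning), the cross-product is taken over genes, and the result is
#' rescaled to a mean diagonal of 1.
#'
#' @param abundances Numeric lines x genes matrix (already normalised
#'   abundances; rows named by line).
#' @return A `kernel_matrix` with kind `"T"`.
#' @export
transcriptome_kernel <- function(abundances) {
  abundances <- as.matrix(abundances)
  if (anyNA(abundances)) abort("abundance matrix contains missing values")
  sds <- apply(abundances, 2, sd)
  keep <- sds > 0
  if (!any(keep)) abort("all genes have zero variance")
  if (any(!keep)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(!keep)),
         class = "omicblup_zero_variance_genes")
  }
  Z <- scale(abundances[, keep, drop = FALSE])
  Tk <- tcrossprod(Z) / ncol(Z)
  Tk <- Tk / mean(diag(Tk))
  kernel_matrix(Tk, kind = "T",
                axis_ids = rownames(abundances) %||%
                  sprintf("L%03d", seq_len(nrow(abundances))))
}

#' Gaussian (RKHS) kernel
#'
#' Nonlinear reproducing kernel over marker (or feature) profiles:
#' `K[i,j] = exp(-d2[i,j] / h)` with `d2` the squared Euclidean distance
#' between rows and `h` a bandwidth controlling how fast correlation decays
#' with distance. A single Gaussian kernel on SNP profiles captures additive
#' effects together with cryptic epistatic and dominance interactions, which
#' is why the RKHS scenarios fit one `G*` term instead of separate G, G#G
#' and A terms.
#'
#' @param X Numeric lines x features matrix (e.g. centred genotypes).
#' @param h Positive bandwidth. Default: median of the nonzero pairwise
#'   squared distances (logged in the result's `bandwidth` attribute).
#' @param scale_features Divide each squared distance by the feature count,
#'   making `h` comparable across marker densities (default `FALSE`).
#' @return A `kernel_matrix` with kind `"GAUSS"`, unit diagonal.
#' @export
#' @examples
#' gaussian_kernel(rbind(a = c(0, 0), b = c(3, 4)), h = 25)  # off-diag exp(-1)
gaussian_kernel <- function(X, h = NULL, scale_features = FALSE) {
  X <- as.matrix(X)
  d2 <- as.matrix(dist(X))^2
  if (scale_features) d2 <- d2 / ncol(X)
  if (is.null(h)) {
    nz <- d2[upper.tri(d2)]
    nz <- nz[nz > 0]
    if (length(nz) == 0) abort("all rows identical: cannot pick a bandwidth")
    h <- median(nz)
  }
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    abort("bandwidth h must be a positive scalar")
  }
  K <- exp(-d2 / h)
  diag(K) <- 1
  kernel_matrix(K, kind = "GAUSS", bandwidth = h,
                axis_ids = rownames(X) %||% sprintf("L%03d", seq_len(nrow(X))))
}

#' Incidence matrix relating observations to groups
#'
#' Builds the 0/1 matrix `Z` (observations x groups) that expands group-level
#' (line- or environment-level) effects to the observation level: each row
#' has exactly one 1, and column sums equal replicate counts.
#'
#' @param groups Vector (or factor) giving each observation's group, in
#'   observation order; names (if any) are used as observation ids.
#' @param levels Ordered group levels defining the column order; defaults to
#'   the order of first appearance.
#' @param obs_ids Optional observation ids (row names).
#' @return A 0/1 matrix of class `incidence_matrix`.
#' @export
#' @examples
#' Z <- incidence_matrix(rep(c("l1", "l2", "l3"), times = c(5, 3, 2)))
#' colSums(Z)
incidence_matrix <- function(groups, levels = NULL, obs_ids = NULL) {
  if (is.null(levels)) levels <- unique(as.character(groups))
  g <- as.character(groups)
  bad <- which(is.na(g) | !g %in% levels)
  if (length(bad) > 0) {
    ids <- obs_ids %||% names(groups) %||% as.character(bad)
    abort(paste0("observation(s) not mapped to a listed group: ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  Z <- matrix(0, nrow = length(g), ncol = length(levels),
              dimnames = list(obs_ids %||% names(groups) %||%
                                sprintf("obs%03d", seq_along(g)),
                              levels))
  Z[cbind(seq_along(g), match(g, levels))] <- 1
  structure(Z, class = c("incidence_matrix", "matrix", "array"))
}

#' Multi-environment G x E block kernel
#'
#' Observation-level genotype-by-environment covariance under the
#' multi-environment single-variance model:
#' `(Zg G Zg') o (Ze Ze')` -- the Hadamard product of the observation-expanded
#' genomic kernel with the same-environment indicator. With observations
#' sorted by environment this is block-diagonal: within-environment blocks
#' equal the expanded `G`, cross-environment blocks are exactly zero.
#'
#' @param G Line-level `kernel_matrix` (additive or Gaussian).
#' @param Zg Observations x lines [incidence_matrix()].
#' @param Ze Observations x environments [incidence_matrix()] sharing `Zg`'s
#'   observation ordering.
#' @return A `kernel_matrix` with kind `"GxE"` over observations.
#' @export
gxe_block_kernel <- function(G, Zg, Ze) {
  if (nrow(Zg) != nrow(Ze) || !identical(rownames(Zg), rownames(Ze))) {
    abort("Zg and Ze must share the same observation ordering")
  }
  if (ncol(Zg) != nrow(G)) abort("Zg columns must match kernel axis")
  Kobs <- Zg %*% unclass(G) %*% t(Zg)
  Kobs <- Kobs * tcrossprod(Ze)
  kernel_matrix(Kobs, kind = "GxE", axis_ids = rownames(Zg))
}
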