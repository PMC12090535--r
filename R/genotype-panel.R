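#' Assemble a genotype panel from a marker code matrix
#'
#' A genotype panel holds biallelic SNP codes for a set of inbred or partially
#' inbred lines together with the per-marker allele frequencies every genomic
#' kernel needs. Codes are stored as minor/alternate allele dosages in
#' `{0, 1, 2}`; matrices supplied in the `{-1, 0, 1}` dialect are detected from
#' the observed value set and shifted. Value sets compatible with both dialects
#' (for example only `0` and `1` present) are rejected rather than guessed.
#'
#' Missing codes are mean-imputed per marker (with the marker mean `2 p_k`)
#' before frequencies are finalised, so downstream centring sees a complete
#' matrix.
#'
#' @param codes Integer-like matrix, lines in rows and markers in columns, in
#'   `{0,1,2}` or `{-1,0,1}`. Row names are taken as line ids (generated when
#'   absent); column names as marker ids.
#' @param line_ids Optional character vector overriding row names.
#'
#' @return An object of class `genotype_panel`: a list with `codes` (l x m
#'   matrix in `{0,1,2}`, possibly fractional where imputed), `line_ids`,
#'   `allele_freq` (per-marker `p_k`), and `n_imputed` (count of imputed
#'   cells).
#' @seealso [grm_linear()], [dominance_kernel()], [simulate_genotypes()]
#' @export
#' @examples
#' gp <- genotype_panel(matrix(c(0, 1, 2), ncol = 1,
#'                             dimnames = list(c("a", "b", "c"), "m1")))
#' gp$allele_freq
genotype_panel <- function(codes, line_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(line_ids)) {
    line_ids <- rownames(codes) %||% sprintf("L%03d", seq_len(nrow(codes)))
  }
  if (anyDuplicated(line_ids)) {
    abort(paste0("duplicated line id(s): ",
                 paste(unique(line_ids[duplicated(line_ids)]), collapse = ", ")))
  }
  rownames(codes) <- line_ids
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("M%05d", seq_len(ncol(codes)))
  }
  obs <- sort(unique(as.vector(codes[!is.na(codes)])))
  if (length(obs) == 0) abort("genotype matrix has no non-missing codes")
  if (any(!obs %in% c(-1, 0, 1, 2))) {
    abort("genotype codes must lie in {0,1,2} or {-1,0,1}")
  }
  if (any(obs == -1)) {
    codes <- codes + 1            # {-1,0,1} dialect
  } else if (!any(obs == 2) && any(obs == 1)) {
    abort(paste0("ambiguous genotype coding: observed values {",
                 paste(obs, collapse = ","),
                 "} fit both {0,1,2} and {-1,0,1}; recode explicitly"))
  }
  n_imputed <- sum(is.na(codes))
  if (n_imputed > 0) {
    for (k in which(colSums(is.na(codes)) > 0)) {
      mk <- mean(codes[, k], na.rm = TRUE)
      codes[is.na(codes[, k]), k] <- mk
    }
  }
  structure(
    list(codes = codes,
         line_ids = line_ids,
         allele_freq = colMeans(codes) / 2,
         n_imputed = n_imputed),
    class = "genotype_panel"
  )
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d lines x %d markers\n",
              nrow(x$codes), ncol(x$codes)))
  cat(sprintf("  allele freq range: %.3f - %.3f; imputed cells: %d\n",
              min(x$allele_freq), max(x$allele_freq), x$n_imputed))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$codes)

is_polymorphic <- function(panel, eps = .Machine$double.eps^0.5) {
  p <- panel$allele_freq
  p > eps & p < 1 - eps
}

#' Centre a genotype matrix by twice the allele frequency
#'
#' Produces the centred marker matrix `W` with `W[i,k] = X[i,k] - 2 p_k`,
#' where `p_k = (2l)^-1 sum_i X[i,k]`. Monomorphic markers (`p_k` of 0 or 1)
#' carry no information and are dropped with a warning; the retained marker
#' ids are recorded in the `"markers"` attribute.
#'
#' @param panel A [genotype_panel()].
#' @return Numeric l x (retained m) matrix with column means zero.
#' @export
center_genotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- is_polymorphic(panel)
  if (!any(keep)) abort("all markers are monomorphic; nothing to centre")
  if (any(!keep)) {
    warn(sprintf("dropping %d monomorphic marker(s): %s",
                 sum(!keep),
                 paste(head(colnames(panel$codes)[!keep], 5), collapse = ", ")),
         class = "omicblup_monomorphic")
  }
  X <- panel$codes[, keep, drop = FALSE]
  W <- sweep(X, 2, 2 * panel$allele_freq[keep], "-")
  attr(W, "markers") <- colnames(X)
  W
}
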