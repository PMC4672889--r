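# TPM computation and spike-in anchored cross-library scaling.

#' Compute TPM from a fractionated experiment
#'
#' `TPM(g, j) = 1e6 * (c(g,j)/L_g) / sum_{g' non-spike} (c(g',j)/L_{g'})`.
#' Spike-in rows are carried through with the same per-sample denominator
#' but excluded from it, so biological TPMs stay comparable when spike mass
#' varies between libraries.
#'
#' @param exp a [fracseq_experiment()].
#' @return An `expression_matrix`: list with `values` (gene x sample TPM
#'   matrix), `spike` (logical per row), `normalized` (FALSE until
#'   [apply_factors()]), and the experiment's sample sheet.
#' @export
compute_tpm <- function(exp) {
  rate <- exp$counts / exp$lengths
  spike <- rownames(exp$counts) %in% exp$spikein_ids
  denom <- colSums(rate[!spike, , drop = FALSE])
  if (any(denom == 0))
    fs_stop(paste0("all-zero sample(s), TPM undefined: ",
                   paste(colnames(exp$counts)[denom == 0], collapse = ", ")),
            "validation")
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  structure(list(values = tpm, spike = setNames(spike, rownames(tpm)),
                 normalized = FALSE, sheet = exp$sheet),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "rows x", ncol(x$values),
      "samples (TPM,", if (x$normalized) "spike-normalized)" else "raw)", "\n")
  invisible(x)
}

#' Spike-in anchored scale factors (median-of-ratios)
#'
#' For each usable spike-in i the reference `r_i` is the geometric mean of
#' its counts across samples; spikes with a zero count in any sample are
#' dropped (a zero would put -Inf into the log-mean). The factor for sample
#' j is `median_i c(i,j) / r_i`, and factors are rescaled to geometric mean
#' 1 so they carry no overall size information.
#'
#' An optional rank-`ruv_k` smoothing of the residual spike log-count
#' matrix (SVD components added back to the log factors) is available for
#' experiments with structured unwanted variation; it is off by default.
#'
#' @param exp a [fracseq_experiment()] with spike-in rows.
#' @param design optional spike-in design; if given, only controls listed in
#'   it are used.
#' @param ruv_k number of unwanted-variation components to absorb (default
#'   0 = plain median-of-ratios).
#' @return named numeric vector of per-sample factors (class
#'   `scale_factors`), geometric mean 1.
#' @export
spikein_factors <- function(exp, design = NULL, ruv_k = 0) {
  ids <- exp$spikein_ids
  if (!is.null(design)) ids <- intersect(ids, design$control_id)
  c_spk <- exp$counts[rownames(exp$counts) %in% ids, , drop = FALSE]
  usable <- rowSums(c_spk == 0) == 0
  c_spk <- c_spk[usable, , drop = FALSE]
  if (nrow(c_spk) < 3)
    fs_stop(paste0("fewer than 3 spike-ins with nonzero counts in every sample (",
                   nrow(c_spk), " usable); fall back to total-count normalization"),
            "validation")
  lc <- log(c_spk)
  r <- exp(rowMeans(lc))
  s <- apply(c_spk / r, 2, median)
  if (ruv_k > 0) {
    resid <- lc - rowMeans(lc) - rep(log(s), each = nrow(lc))
    sv <- svd(resid, nu = ruv_k, nv = ruv_k)
    kk <- min(ruv_k, length(sv$d))
    approx_k <- sv$u[, seq_len(kk), drop = FALSE] %*%
      (sv$d[seq_len(kk)] * t(sv$v[, seq_len(kk), drop = FALSE]))
    s <- s * exp(colMeans(approx_k))
  }
  s <- s / exp(mean(log(s)))
  structure(setNames(s, colnames(exp$counts)), class = "scale_factors",
            constraint = "geometric mean 1")
}

#' Apply scale factors to an expression matrix
#'
#' Divides column j by `s_j` and flags the matrix as spike-normalized.
#'
#' @param mat an `expression_matrix` from [compute_tpm()].
#' @param s positive per-sample factors matching the matrix columns.
#' @return The rescaled `expression_matrix`.
#' @export
apply_factors <- function(mat, s) {
  if (length(s) != ncol(mat$values))
    fs_stop("length of factors does not match number of samples", "structural")
  if (any(s <= 0)) fs_stop("scale factors must be > 0", "validation")
  if (!is.null(names(s)) && !identical(names(s), colnames(mat$values)))
    s <- s[colnames(mat$values)]
  mat$values <- sweep(mat$values, 2, s, "/")
  mat$normalized <- TRUE
  mat
}
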