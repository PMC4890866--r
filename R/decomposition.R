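#' Eigendecomposition of the positional coevolution matrix
#'
#' Full spectrum, eigenvalues descending, with a deterministic sign
#' convention (the largest-magnitude entry of each eigenvector is made
#' positive).
#'
#' @param Cpos symmetric L x L matrix.
#' @return list of class `sca_spectrum`: `values` (descending), `vectors`
#'   (L x L, columns matched to values).
#' @export
eigendecompose <- function(Cpos) {
  if (max(abs(Cpos - t(Cpos))) > 1e-10) stop("input matrix is not symmetric")
  e <- eigen((Cpos + t(Cpos)) / 2, symmetric = TRUE)
  V <- apply(e$vectors, 2L, function(v) v * sign(v[which.max(abs(v))]))
  structure(list(values = e$values, vectors = V), class = "sca_spectrum")
}

## scramble each column of the code matrix independently (permutation of
## sequences within a column); unweighted per-column counts are invariant
scramble_columns <- function(A) {
  apply(A, 2L, sample)
}

#' Null eigenvalue spectra by column scrambling
#'
#' For each trial, the residues of every alignment column are permuted
#' independently across sequences (sequence weights stay attached to the
#' sequences), the coevolution matrix is recomputed with the same
#' parameters, and its spectrum recorded. Scrambling exactly preserves
#' the unweighted per-column residue counts (asserted).
#'
#' @param processed an `sca_processed`.
#' @param n_trials number of randomization trials (default 10).
#' @param seed integer seed.
#' @param lambda regularizer (default from `processed$params`).
#' @param norm_kind per-pair compression norm.
#' @param bg optional `sca_background` shared across trials.
#' @return `n_trials x L` matrix of descending null eigenvalues.
#' @export
null_spectra <- function(processed, n_trials = 10L, seed = 1L,
                         lambda = NULL, norm_kind = "frobenius", bg = NULL) {
  if (n_trials < 2L) stop("n_trials must be >= 2")
  A <- processed$msa$codes
  counts0 <- apply(A, 2L, tabulate, nbins = 21L)
  if (is.null(bg)) bg <- background(processed,
                                    lambda = processed$params$lambda)
  vals <- withr_seed(seed, {
    vapply(seq_len(n_trials), function(trial) {
      As <- scramble_columns(A)
      stopifnot(identical(apply(As, 2L, tabulate, nbins = 21L), counts0))
      ps <- processed
      ps$msa$codes <- As
      freqs <- compute_frequencies(ps, lambda)
      cons <- conservation_profile(freqs, bg)
      Ct <- weighted_coevolution_tensor(freqs, cons)
      eigendecompose(compress_tensor(Ct, norm_kind))$values
    }, numeric(ncol(A)))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)  # L = 1 case
  t(vals)
}

#' Number of significant eigenmodes
#'
#' The cutoff is the mean of the second-ranked null eigenvalue across
#' trials plus two standard deviations (the first null eigenvalue is a
#' trivial consequence of per-column conservation and is ignored);
#' `k*` counts actual eigenvalues above the cutoff, from the top and
#' including the first mode.
#'
#' @param spectrum an `sca_spectrum`.
#' @param null_values matrix from [null_spectra()].
#' @return list with `k_star` and `cutoff`.
#' @export
select_k_star <- function(spectrum, null_values) {
  if (is.null(dim(null_values)) || nrow(null_values) < 2L)
    stop("null spectra from >= 2 trials required")
  lam2 <- null_values[, 2L]
  cutoff <- mean(lam2) + 2 * stats::sd(lam2)
  k <- sum(spectrum$values > cutoff)
  list(k_star = as.integer(k), cutoff = cutoff)
}

## excess kurtosis
.kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Independent component analysis of the top eigenmodes
#'
#' Rotates the `k*` retained eigenvectors into maximally independent
#' components with an infomax natural-gradient iteration (logistic /
#' tanh score, appropriate for the sparse, super-Gaussian loading
#' patterns of coevolution modes). The ICs span the same subspace as the
#' input eigenmodes. Each IC is sign-oriented so its largest-magnitude
#' loading is positive; ICs are ordered by the index of their dominant
#' eigenmode (ties broken by descending excess kurtosis).
#'
#' @param V_topk L x k matrix of retained eigenvectors.
#' @param learn_rate gradient step (default 0.1).
#' @param max_iter maximum iterations (default 1e5).
#' @param tol convergence threshold on the relative update norm
#'   (default 1e-7).
#' @param seed integer seed (the iteration is deterministic from the
#'   identity start; the seed is recorded for provenance).
#' @return list of class `sca_ica`: `W` (k x k unmixing matrix), `ICs`
#'   (L x k, columns are independent components, `ICs = V W^T`),
#'   `iterations_run`, `converged`, `seed`.
#' @export
ica <- function(V_topk, learn_rate = 0.1, max_iter = 1e5, tol = 1e-7,
                seed = 1L) {
  V_topk <- as.matrix(V_topk)
  k <- ncol(V_topk)
  L <- nrow(V_topk)
  if (k < 1L) stop("at least one eigenmode required")
  if (k == 1L) {
    ic <- V_topk * sign(V_topk[which.max(abs(V_topk)), 1L])
    return(structure(list(W = matrix(1, 1, 1), ICs = ic,
                          iterations_run = 0L, converged = TRUE,
                          seed = as.integer(seed)), class = "sca_ica"))
  }
  X <- t(V_topk)                      # k x L signal matrix
  W <- diag(k)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    U <- W %*% X
    g <- 1 - 2 / (1 + exp(-U))        # = -tanh(U/2) score
    dW <- learn_rate * (diag(k) + g %*% t(U) / L) %*% W
    W <- W + dW
    if (max(abs(dW)) / max(abs(W)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICA did not converge in ", max_iter, " iterations")
  ICs <- V_topk %*% t(W)
  ## orient each IC: largest-|loading| positive
  flip <- vapply(seq_len(k), function(p)
    sign(ICs[which.max(abs(ICs[, p])), p]), numeric(1))
  flip[flip == 0] <- 1
  ICs <- sweep(ICs, 2L, flip, `*`)
  W <- W * flip
  ## order by dominant eigenmode, then descending kurtosis
  dom <- apply(abs(W), 1L, which.max)
  kur <- apply(ICs, 2L, .kurtosis)
  ord <- order(dom, -kur)
  structure(list(W = W[ord, , drop = FALSE],
                 ICs = ICs[, ord, drop = FALSE],
                 iterations_run = it, converged = converged,
                 seed = as.integer(seed)), class = "sca_ica")
}

#' Spectrum, null, k-star and ICA in one call
#'
#' @param coevo an `sca_coevolution`.
#' @param processed the `sca_processed` the coevolution was computed on.
#' @param n_trials randomization trials for the null (default 10).
#' @param seed integer seed.
#' @return list of class `sca_decomposition`: `spectrum`, `null_values`,
#'   `k_star`, `cutoff`, `ica` (`NULL` when `k_star == 0`).
#' @export
decompose <- function(coevo, processed, n_trials = 10L, seed = 1L) {
  spec <- eigendecompose(coevo$Cpos)
  nulls <- null_spectra(processed, n_trials = n_trials, seed = seed,
                        lambda = coevo$freqs$lambda,
                        norm_kind = coevo$norm_kind, bg = coevo$bg)
  ks <- select_k_star(spec, nulls)
  ic <- NULL
  if (ks$k_star > 0L)
    ic <- ica(spec$vectors[, seq_len(ks$k_star), drop = FALSE], seed = seed)
  structure(list(spectrum = spec, null_values = nulls,
                 k_star = ks$k_star, cutoff = ks$cutoff, ica = ic),
            class = "sca_decomposition")
}
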