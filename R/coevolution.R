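#' Background amino-acid distribution
#'
#' Returns the background distribution used by the conservation and
#' coevolution statistics. The default table (`AA_BACKGROUND`) contains
#' amino-acid frequencies computed over a non-redundant protein sequence
#' database; `mode = "alignment"` instead estimates q from the pooled,
#' weighted frequencies of the alignment itself. The gap background
#' `qbar0` is the alignment's overall weighted gap fraction (0 for a
#' gap-free alignment), and the gap-adjusted vector is
#' `qbar_a = (1 - qbar0) * q_a`.
#'
#' @param processed an `sca_processed` (used for the gap fraction and,
#'   in alignment mode, for q itself).
#' @param q_table optional user-supplied 20-vector of amino-acid
#'   frequencies (must sum to 1 within 1e-6).
#' @param mode `"database"` (packaged table) or `"alignment"`.
#' @param lambda regularizer used for the alignment-mode estimate and
#'   the gap floor.
#' @return list of class `sca_background`: `q` (20), `qbar0` (scalar),
#'   `qbar` (length 21: gap then 20 amino acids).
#' @export
background <- function(processed, q_table = NULL,
                       mode = c("database", "alignment"), lambda = 0.03) {
  mode <- match.arg(mode)
  A <- processed$msa$codes
  w <- processed$weights$w
  if (!is.null(q_table)) {
    if (length(q_table) != 20L) stop("q table must have 20 entries")
    if (abs(sum(q_table) - 1) > 1e-6)
      stop("q table must sum to 1 (got ", sum(q_table), ")")
    q <- q_table / sum(q_table)
  } else if (mode == "database") {
    q <- unname(AA_BACKGROUND / sum(AA_BACKGROUND))
  } else {
    counts <- vapply(seq_along(AA_ALPHABET), function(a)
      sum(w * rowSums(A == a)), numeric(1))
    q <- (1 - lambda) * counts / sum(counts) + lambda / 20
  }
  qbar0 <- sum(w * rowMeans(A == 0L)) / sum(w)
  structure(list(q = q, qbar0 = qbar0, qbar = c(qbar0, (1 - qbar0) * q)),
            class = "sca_background")
}

#' Weighted, regularized frequency tables
#'
#' Single-position frequencies over 21 states (gap + 20 amino acids),
#' `f_i^a = (1 - lambda) sum_s w_s x_sia / M_eff + lambda / 21`, and
#' pairwise amino-acid frequencies (gap excluded from the pair table),
#' `f_ij^ab = (1 - lambda) sum_s w_s x_sia x_sjb / M_eff + lambda / 21^2`,
#' stored as a dense `20L x 20L` matrix in position-major blocks.
#'
#' @param processed an `sca_processed`.
#' @param lambda regularizer in `[0, 1)`; defaults to the value in
#'   `processed$params`.
#' @return list of class `sca_freqs`: `f1` (L x 21, column 1 = gap),
#'   `f2` (20L x 20L), `lambda`, `M_eff`.
#' @export
compute_frequencies <- function(processed, lambda = NULL) {
  if (is.null(lambda)) lambda <- processed$params$lambda
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  A <- processed$msa$codes
  w <- processed$weights$w
  Meff <- sum(w)
  if (Meff <= 0) stop("M_eff must be positive")
  M <- nrow(A); L <- ncol(A)

  f1raw <- matrix(0, L, 21L)
  for (a in 0:20) f1raw[, a + 1L] <- colSums(w * (A == a)) / Meff
  f1 <- (1 - lambda) * f1raw + lambda / 21

  ## sparse M x 20L indicator (gaps are all-zero rows within a block)
  nz <- which(A != 0L, arr.ind = TRUE)
  X <- Matrix::sparseMatrix(i = nz[, 1L],
                            j = (nz[, 2L] - 1L) * 20L + A[nz],
                            x = 1, dims = c(M, 20L * L))
  f2raw <- as.matrix(Matrix::crossprod(X, X * w)) / Meff
  f2 <- (1 - lambda) * f2raw + lambda / 441

  structure(list(f1 = f1, f2 = f2, lambda = lambda, M_eff = Meff),
            class = "sca_freqs")
}

#' Kullback-Leibler relative entropy of a binary frequency
#'
#' `D(f, q) = f log(f/q) + (1-f) log((1-f)/(1-q))`, in nats. Vectorized.
#'
#' @param f observed frequency in (0, 1).
#' @param q background frequency in (0, 1).
#' @return relative entropy (>= 0, zero iff `f == q`).
#' @export
relative_entropy <- function(f, q) {
  if (any(f <= 0 | f >= 1) || any(q <= 0 | q >= 1))
    stop("relative_entropy requires f, q in (0, 1)")
  f * log(f / q) + (1 - f) * log((1 - f) / (1 - q))
}

#' Conservation gradient weights
#'
#' `phi(f, q) = d D / d f = log( f (1 - q) / ((1 - f) q) )`; zero at
#' `f = q`, signed (negative when `f < q`).
#'
#' @inheritParams relative_entropy
#' @return gradient weight.
#' @export
phi_weights <- function(f, q) {
  if (any(f <= 0 | f >= 1) || any(q <= 0 | q >= 1))
    stop("phi_weights requires f, q in (0, 1)")
  log(f * (1 - q) / ((1 - f) * q))
}

#' Position-specific conservation profile
#'
#' Per-amino-acid relative entropies `D_i^a` and gradient weights
#' `phi_i^a` against the plain background `q`, and the overall positional
#' conservation `D_i = sum_{a=0..20} f_i^a log(f_i^a / qbar^a)` over all
#' 21 states against the gap-adjusted background. Since the regularized
#' frequencies put mass `lambda/21` on the gap state even in a gap-free
#' alignment, the gap background entering `D_i` is floored at
#' `lambda/21` to keep `D_i` finite (numerical choice; `bg$qbar0` itself
#' is left untouched).
#'
#' @param freqs an `sca_freqs`.
#' @param bg an `sca_background`.
#' @return list of class `sca_conservation`: `Dia` (L x 20), `Di`
#'   (length L), `phi` (L x 20).
#' @export
conservation_profile <- function(freqs, bg) {
  fa <- freqs$f1[, -1L, drop = FALSE]           # amino columns
  qm <- matrix(bg$q, nrow(fa), 20L, byrow = TRUE)
  Dia <- relative_entropy(fa, qm)
  phi <- phi_weights(fa, qm)
  qb <- bg$qbar
  qb[1L] <- max(qb[1L], freqs$lambda / 21)
  qbar <- matrix(qb, nrow(fa), 21L, byrow = TRUE)
  terms <- ifelse(freqs$f1 > 0, freqs$f1 * log(freqs$f1 / qbar), 0)
  Di <- rowSums(terms)
  structure(list(Dia = Dia, Di = Di, phi = phi),
            class = "sca_conservation")
}

#' Conservation-weighted coevolution tensor
#'
#' Raw amino-acid covariances `C_ij^ab = f_ij^ab - f_i^a f_j^b` weighted
#' by the conservation gradients, `Ct_ij^ab = phi_i^a phi_j^b C_ij^ab`,
#' over the 20 amino acids (gap excluded). Returned as a `20L x 20L`
#' matrix in position-major blocks.
#'
#' @param freqs an `sca_freqs`.
#' @param cons an `sca_conservation`; pass `phi = 1` behaviour by
#'   supplying `flat_phi = TRUE` (plain covariance).
#' @param flat_phi logical; if TRUE the weights are identically 1.
#' @return `20L x 20L` numeric matrix (symmetric).
#' @export
weighted_coevolution_tensor <- function(freqs, cons, flat_phi = FALSE) {
  fvec <- as.vector(t(freqs$f1[, -1L, drop = FALSE]))  # position-major
  C <- freqs$f2 - tcrossprod(fvec)
  if (!flat_phi) {
    phiv <- as.vector(t(cons$phi))
    C <- C * tcrossprod(phiv)
  }
  C
}

#' Compress the coevolution tensor to a positional matrix
#'
#' Collapses each 20 x 20 amino-acid block of the tensor to a scalar:
#' the Frobenius norm (root-sum-of-squares; default) or the spectral
#' norm (top singular value).
#'
#' @param Ct `20L x 20L` tensor from [weighted_coevolution_tensor()].
#' @param norm_kind `"frobenius"` or `"spectral"`.
#' @return symmetric nonnegative `L x L` matrix.
#' @export
compress_tensor <- function(Ct, norm_kind = c("frobenius", "spectral")) {
  norm_kind <- match.arg(norm_kind)
  L <- nrow(Ct) / 20L
  stopifnot(L == round(L))
  if (norm_kind == "frobenius") {
    G <- Matrix::sparseMatrix(i = seq_len(20L * L),
                              j = rep(seq_len(L), each = 20L), x = 1)
    out <- sqrt(as.matrix(Matrix::crossprod(G, Ct^2 %*% G)))
  } else {
    out <- matrix(0, L, L)
    for (i in seq_len(L)) {
      bi <- ((i - 1L) * 20L + 1L):(i * 20L)
      for (j in i:L) {
        bj <- ((j - 1L) * 20L + 1L):(j * 20L)
        out[i, j] <- out[j, i] <- svd(Ct[bi, bj], nu = 0, nv = 0)$d[1L]
      }
    }
  }
  dimnames(out) <- NULL
  out
}

#' Amino-acid projection and reduced alignment
#'
#' Builds the per-position projection
#' `Pbar_i^a = phi_i^a f_i^a / sqrt(sum_b (phi_i^b f_i^b)^2)` and the
#' reduced M x L alignment `x_si = sum_a Pbar_i^a x_sia` (0 at gaps).
#' Columns with a zero-norm projection are flagged and set to zero.
#'
#' @param processed an `sca_processed`.
#' @param cons an `sca_conservation`.
#' @param freqs an `sca_freqs`.
#' @return list of class `sca_projection`: `Pbar` (L x 20, unit rows),
#'   `x` (M x L), `degenerate` (integer vector of flagged columns).
#' @export
projection_and_reduce <- function(processed, cons, freqs) {
  fa <- freqs$f1[, -1L, drop = FALSE]
  pf <- cons$phi * fa
  nrm <- sqrt(rowSums(pf^2))
  degenerate <- which(nrm == 0)
  nrm[nrm == 0] <- 1
  Pbar <- pf / nrm
  Pbar[degenerate, ] <- 0
  A <- processed$msa$codes
  x <- matrix(0, nrow(A), ncol(A))
  nz <- which(A != 0L, arr.ind = TRUE)
  x[nz] <- Pbar[cbind(nz[, 2L], A[nz])]
  structure(list(Pbar = Pbar, x = x, degenerate = degenerate),
            class = "sca_projection")
}

#' Full coevolution computation for a processed alignment
#'
#' Convenience wrapper: frequencies, background, conservation, weighted
#' tensor, positional compression, projection and reduced alignment.
#'
#' @param processed an `sca_processed`.
#' @param lambda regularizer (default from `processed$params`).
#' @param norm_kind per-pair compression norm.
#' @param bg optional `sca_background` (default packaged table).
#' @param keep_tensor logical; retain the 20L x 20L tensor in the result
#'   (memory grows as (20 L)^2).
#' @return list of class `sca_coevolution`: `Cpos` (L x L), `freqs`,
#'   `bg`, `conservation`, `projection`, `norm_kind`, optionally
#'   `tensor`.
#' @export
coevolution_matrix <- function(processed, lambda = NULL,
                               norm_kind = c("frobenius", "spectral"),
                               bg = NULL, keep_tensor = FALSE) {
  norm_kind <- match.arg(norm_kind)
  freqs <- compute_frequencies(processed, lambda)
  if (is.null(bg)) bg <- background(processed, lambda = freqs$lambda)
  cons <- conservation_profile(freqs, bg)
  Ct <- weighted_coevolution_tensor(freqs, cons)
  Cpos <- compress_tensor(Ct, norm_kind)
  proj <- projection_and_reduce(processed, cons, freqs)
  out <- list(Cpos = Cpos, freqs = freqs, bg = bg, conservation = cons,
              projection = proj, norm_kind = norm_kind)
  if (keep_tensor) out$tensor <- Ct
  structure(out, class = "sca_coevolution")
}
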