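#' Default preprocessing parameters
#'
#' Cutoffs follow the standard SCA defaults: positions with a raw gap
#' fraction above `pos_gap_cutoff` are truncated (when no reference is
#' used); sequences with gap fraction above `seq_gap_cutoff` or identity
#' to the reference below `min_ref_identity` are removed; sequence
#' weights use the `weight_identity_threshold` neighborhood; positions
#' with weighted gap frequency above `weighted_pos_gap_cutoff` are
#' truncated; `lambda` regularizes frequencies; optional weighted
#' resampling draws `resample_factor * M_eff` sequences.
#'
#' @param pos_gap_cutoff raw per-column gap fraction cutoff (default 0.4).
#' @param seq_gap_cutoff per-sequence gap fraction cutoff, gamma_seq
#'   (default 0.2).
#' @param min_ref_identity minimum fractional identity to the reference,
#'   Delta (default 0.2).
#' @param weight_identity_threshold identity threshold delta for the
#'   weight neighborhoods (default 0.8).
#' @param weighted_pos_gap_cutoff weighted per-column gap frequency
#'   cutoff, gamma_pos (default 0.2).
#' @param lambda frequency regularizer in `[0, 1)` (default 0.03).
#' @param resample logical; draw a weighted subsample (default FALSE).
#' @param resample_factor target size as a multiple of `M_eff`
#'   (default 1.5).
#' @param seed integer seed for the resampling draw.
#' @return a list of class `sca_params`.
#' @export
preprocess_params <- function(pos_gap_cutoff = 0.4, seq_gap_cutoff = 0.2,
                              min_ref_identity = 0.2,
                              weight_identity_threshold = 0.8,
                              weighted_pos_gap_cutoff = 0.2, lambda = 0.03,
                              resample = FALSE, resample_factor = 1.5,
                              seed = 1L) {
  p <- list(pos_gap_cutoff = pos_gap_cutoff, seq_gap_cutoff = seq_gap_cutoff,
            min_ref_identity = min_ref_identity,
            weight_identity_threshold = weight_identity_threshold,
            weighted_pos_gap_cutoff = weighted_pos_gap_cutoff,
            lambda = lambda, resample = resample,
            resample_factor = resample_factor, seed = as.integer(seed))
  cuts <- unlist(p[c("pos_gap_cutoff", "seq_gap_cutoff", "min_ref_identity",
                     "weight_identity_threshold",
                     "weighted_pos_gap_cutoff")])
  if (any(cuts < 0 | cuts > 1)) stop("cutoffs must lie in [0, 1]")
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  if (resample_factor < 1) stop("resample_factor must be >= 1")
  class(p) <- "sca_params"
  p
}

#' Fractional identity between two aligned rows
#'
#' Number of columns where both rows carry the same amino acid (gap-gap
#' columns are not matches), divided by the full alignment length.
#'
#' @param r,s aligned rows (character strings or integer code vectors).
#' @return fractional identity in `[0, 1]`.
#' @export
fractional_identity <- function(r, s) {
  if (is.character(r)) r <- encode_rows(r)[1L, ]
  if (is.character(s)) s <- encode_rows(s)[1L, ]
  if (length(r) != length(s)) stop("length mismatch")
  sum(r == s & r != 0L) / length(r)
}

#' All-pairs fractional identity matrix
#'
#' @param codes integer code matrix (M x L, 0 = gap).
#' @return symmetric M x M matrix of fractional identities.
#' @export
identity_matrix <- function(codes) {
  M <- nrow(codes); L <- ncol(codes)
  S <- matrix(0, M, M)
  for (a in seq_along(AA_ALPHABET)) {
    Xa <- (codes == a) * 1
    S <- S + tcrossprod(Xa)
  }
  S / L
}

#' Truncate gapped alignment columns
#'
#' Reference mode keeps the columns where the reference sequence is
#' ungapped; cutoff mode keeps columns whose raw gap fraction is at most
#' `gap_cutoff`.
#'
#' @param msa an `sca_msa`.
#' @param reference_id reference sequence id (reference mode) or `NULL`.
#' @param gap_cutoff raw gap-fraction cutoff (cutoff mode).
#' @return list with `msa` (truncated) and `kept` (logical column mask).
#' @export
truncate_positions <- function(msa, reference_id = NULL, gap_cutoff = 0.4) {
  if (!is.null(reference_id)) {
    ri <- match(reference_id, msa$ids)
    if (is.na(ri)) stop("unknown reference_id: ", reference_id)
    kept <- msa$codes[ri, ] != 0L
  } else {
    kept <- colMeans(msa$codes == 0L) <= gap_cutoff
  }
  if (!any(kept)) stop("all columns removed")
  list(msa = msa_subset(msa, cols = kept), kept = kept)
}

#' Filter gappy and reference-divergent sequences
#'
#' Removes sequences with gap fraction above `seq_gap_cutoff`, then
#' sequences with fractional identity to the reference below
#' `min_ref_identity`. The reference itself is never removed.
#'
#' @param msa an `sca_msa`.
#' @param seq_gap_cutoff gamma_seq.
#' @param reference_id optional reference id (identity filter applies
#'   only when given).
#' @param min_ref_identity Delta.
#' @return list with `msa`, `removed_gap` and `removed_identity`
#'   (character id vectors).
#' @export
filter_sequences <- function(msa, seq_gap_cutoff = 0.2, reference_id = NULL,
                             min_ref_identity = 0.2) {
  gapfrac <- rowMeans(msa$codes == 0L)
  keep <- gapfrac <= seq_gap_cutoff
  ri <- NA_integer_
  if (!is.null(reference_id)) {
    ri <- match(reference_id, msa$ids)
    if (is.na(ri)) stop("unknown reference_id: ", reference_id)
    keep[ri] <- TRUE
  }
  removed_gap <- msa$ids[!keep]
  removed_identity <- character(0)
  if (!is.null(reference_id)) {
    ref <- msa$codes[ri, ]
    idref <- colSums(t(msa$codes) == ref & ref != 0L) / msa$L
    drop_id <- keep & idref < min_ref_identity
    drop_id[ri] <- FALSE
    removed_identity <- msa$ids[drop_id]
    keep <- keep & !drop_id
  }
  if (sum(keep) < 2L) stop("fewer than 2 sequences remain after filtering")
  list(msa = msa_subset(msa, seqs = keep), removed_gap = removed_gap,
       removed_identity = removed_identity)
}

#' Sequence weights against phylogenetic redundancy
#'
#' Each sequence is down-weighted by the size of its identity
#' neighborhood: `w_s = 1 / #\{r : S_rs > delta\}` (the neighborhood
#' includes `s` itself since `S_ss = 1`). The effective number of
#' sequences is `M_eff = sum(w)`.
#'
#' @param msa an `sca_msa`.
#' @param delta identity threshold (strict inequality), default 0.8.
#' @return list of class `sca_weights` with `w` and `M_eff`.
#' @export
compute_weights <- function(msa, delta = 0.8) {
  S <- identity_matrix(msa$codes)
  ## self-identity of a gapped row is < 1 under the gap-gap convention;
  ## the neighborhood must nevertheless include s itself (S_ss := 1)
  diag(S) <- 1
  w <- 1 / rowSums(S > delta)
  structure(list(w = w, M_eff = sum(w)), class = "sca_weights")
}

#' Truncate columns by weighted gap frequency
#'
#' Removes columns whose weighted gap frequency
#' `f0_i = 1 - sum_s w_s x_si / sum_s w_s` exceeds `gamma_pos`, then
#' recomputes the sequence weights on the truncated alignment.
#'
#' @param msa an `sca_msa`.
#' @param weights an `sca_weights` computed on `msa`.
#' @param gamma_pos weighted gap-frequency cutoff.
#' @param delta identity threshold used to recompute weights.
#' @return list with `msa`, `kept` mask and recomputed `weights`.
#' @export
truncate_weighted_gapped_positions <- function(msa, weights, gamma_pos = 0.2,
                                               delta = 0.8) {
  w <- weights$w
  f0 <- colSums(w * (msa$codes == 0L)) / sum(w)
  kept <- f0 <= gamma_pos
  if (!any(kept)) stop("all columns removed")
  out <- msa_subset(msa, cols = kept)
  list(msa = out, kept = kept, weights = compute_weights(out, delta))
}

#' Weighted resampling of sequences
#'
#' Draws `round(factor * M_eff)` distinct sequences without replacement
#' with selection probability proportional to the sequence weights,
#' producing a smaller alignment with an approximately preserved
#' effective number of sequences. A no-op (with a warning) when the
#' target size reaches `M`.
#'
#' @param msa an `sca_msa`.
#' @param weights an `sca_weights` on `msa`.
#' @param factor multiple of `M_eff` to draw (default 1.5).
#' @param seed integer seed.
#' @param keep_id optional id always included in the sample.
#' @return list with `msa` and `index` of retained sequences.
#' @export
resample_sequences <- function(msa, weights, factor = 1.5, seed = 1L,
                               keep_id = NULL) {
  target <- round(factor * weights$M_eff)
  if (target >= msa$M) {
    warning("resampling target >= M; returning alignment unchanged")
    return(list(msa = msa, index = seq_len(msa$M)))
  }
  idx <- withr_seed(seed, sample.int(msa$M, target, replace = FALSE,
                                     prob = weights$w))
  if (!is.null(keep_id)) {
    ri <- match(keep_id, msa$ids)
    if (!is.na(ri) && !(ri %in% idx)) idx[1L] <- ri
  }
  idx <- sort(idx)
  list(msa = msa_subset(msa, seqs = idx), index = idx)
}

## evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Full alignment preprocessing pipeline
#'
#' Runs, in order: (1) column truncation (by reference or raw gap
#' cutoff), (2) gappy-sequence removal, (3) reference-identity filter,
#' (4) sequence weighting and weighted gap-frequency column truncation,
#' (5) weight recomputation on the truncated alignment, and optionally
#' (6) weighted resampling. Every removal is recorded in `provenance`.
#'
#' @param msa an `sca_msa`.
#' @param params an [preprocess_params()] list.
#' @param reference_id optional reference sequence id; when given,
#'   column truncation uses reference mode and a position map is built.
#' @param labels optional residue labels for the reference (see
#'   [build_position_map()]).
#' @return object of class `sca_processed`: `msa`, `weights`
#'   (`sca_weights`), `position_map` (restricted to retained columns; or
#'   `NULL`), `params`, `provenance` (list of step records).
#' @export
preprocess <- function(msa, params = preprocess_params(),
                       reference_id = NULL, labels = NULL) {
  prov <- list()
  note <- function(step, removed, parameter) {
    prov[[length(prov) + 1L]] <<- list(step = step, items_removed = removed,
                                       parameter = parameter)
  }
  pmap <- if (!is.null(reference_id))
    build_position_map(msa, reference_id, labels) else NULL

  ## step 1: column truncation
  tr <- truncate_positions(msa, reference_id,
                           gap_cutoff = params$pos_gap_cutoff)
  note("truncate_positions", which(!tr$kept) - 1L,
       if (is.null(reference_id)) params$pos_gap_cutoff else reference_id)
  cur <- tr$msa
  colmask <- tr$kept

  ## steps 2-3: sequence filters
  fl <- filter_sequences(cur, params$seq_gap_cutoff, reference_id,
                         params$min_ref_identity)
  note("filter_gappy_sequences", fl$removed_gap, params$seq_gap_cutoff)
  note("filter_reference_identity", fl$removed_identity,
       params$min_ref_identity)
  cur <- fl$msa

  ## step 4: weights + weighted gap truncation (recomputes weights, step 5)
  w1 <- compute_weights(cur, params$weight_identity_threshold)
  tw <- truncate_weighted_gapped_positions(cur, w1,
                                           params$weighted_pos_gap_cutoff,
                                           params$weight_identity_threshold)
  removed_cols <- which(colmask)[!tw$kept] - 1L
  note("truncate_weighted_gapped_positions", removed_cols,
       params$weighted_pos_gap_cutoff)
  colmask[colmask] <- tw$kept
  cur <- tw$msa
  weights <- tw$weights

  ## step 6: optional weighted resampling
  if (isTRUE(params$resample)) {
    rs <- resample_sequences(cur, weights, params$resample_factor,
                             params$seed, keep_id = reference_id)
    note("resample_sequences", setdiff(cur$ids, rs$msa$ids),
         params$resample_factor)
    cur <- rs$msa
    weights <- compute_weights(cur, params$weight_identity_threshold)
  }

  if (!is.null(pmap)) {
    pmap <- pmap[colmask, , drop = FALSE]
    rownames(pmap) <- NULL
  }
  structure(list(msa = cur, weights = weights, position_map = pmap,
                 params = params, column_mask = colmask,
                 provenance = prov),
            class = "sca_processed")
}

#' @export
print.sca_processed <- function(x, ...) {
  cat("<sca_processed> ", x$msa$M, " sequences x ", x$msa$L,
      " positions; M_eff = ", round(x$weights$M_eff, 1), "\n", sep = "")
  invisible(x)
}

#' Position labels for a processed alignment
#'
#' Reference labels where a position map exists, otherwise 1-based
#' retained-column indices as characters.
#' @param processed an `sca_processed`.
#' @return character vector of length L.
#' @export
position_labels <- function(processed) {
  if (!is.null(processed$position_map)) {
    lab <- processed$position_map$reference_label
    lab[is.na(lab)] <- paste0("col", which(is.na(lab)))
    lab
  } else {
    as.character(seq_len(processed$msa$L))
  }
}
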