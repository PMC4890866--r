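#' Specification for a planted-sector synthetic alignment
#'
#' Describes the statistical world the generator emulates: a background
#' of independently drawn positions with a stated mixture of
#' near-invariant and neutral sites, planted sectors of co-conserved
#' positions driven by a per-sequence latent on/off state, optional
#' subfamily structure that swaps the preferred residues on a subset of
#' sector positions, and optional redundancy through mutated duplicate
#' sequences.
#'
#' @param M number of (pre-duplication) sequences (default 500).
#' @param L alignment length (default 100).
#' @param q background amino-acid distribution (default packaged table).
#' @param frac_invariant fraction of non-sector positions that are
#'   near-invariant (default 0.10); the rest are neutral.
#' @param invariant_strength probability that a near-invariant position
#'   shows its preferred residue (default 0.9).
#' @param sectors list of sectors, each a list with `positions`
#'   (integer vector), `rho` (coupling strength in `[0, 1]`) and
#'   optionally `preferred` (residue codes 1..20, drawn from q when
#'   absent) and `p_on` (latent-state probability, default 0.5).
#' @param subfamilies list of subfamilies, each a list with `fraction`
#'   (of sequences), `swap_positions` (subset of some sector's
#'   positions) and optionally `swap_to` (replacement residue codes;
#'   defaults to a deterministic shift of the preferred residue).
#'   Fractions must sum to 1 when given; `NULL` means one homogeneous
#'   family.
#' @param dup_factor duplication factor (>= 1; 1 = no duplicates). Each
#'   sequence receives `dup_factor - 1` mutated copies.
#' @param dup_mutation_rate per-position probability that a duplicate
#'   copy is re-drawn from the background (default 0).
#' @param seed integer seed.
#' @return list of class `sca_planted_spec`.
#' @export
planted_spec <- function(M = 500L, L = 100L, q = unname(AA_BACKGROUND),
                         frac_invariant = 0.10, invariant_strength = 0.9,
                         sectors = list(list(positions = 1:10, rho = 0.9),
                                        list(positions = 11:20, rho = 0.9)),
                         subfamilies = NULL, dup_factor = 1,
                         dup_mutation_rate = 0, seed = 1L) {
  all_sector_pos <- unlist(lapply(sectors, `[[`, "positions"))
  if (anyDuplicated(all_sector_pos)) stop("sector position sets overlap")
  if (length(all_sector_pos) && max(all_sector_pos) > L)
    stop("sector positions exceed L")
  rhos <- vapply(sectors, `[[`, numeric(1), "rho")
  if (any(rhos < 0 | rhos > 1)) stop("rho must lie in [0, 1]")
  if (frac_invariant < 0 || frac_invariant > 1)
    stop("frac_invariant must lie in [0, 1]")
  if (dup_factor < 1) stop("dup_factor must be >= 1")
  if (dup_mutation_rate < 0 || dup_mutation_rate > 1)
    stop("dup_mutation_rate must lie in [0, 1]")
  if (!is.null(subfamilies)) {
    fr <- vapply(subfamilies, `[[`, numeric(1), "fraction")
    if (abs(sum(fr) - 1) > 1e-8) stop("subfamily fractions must sum to 1")
  }
  structure(list(M = as.integer(M), L = as.integer(L), q = q / sum(q),
                 frac_invariant = frac_invariant,
                 invariant_strength = invariant_strength,
                 sectors = sectors, subfamilies = subfamilies,
                 dup_factor = dup_factor,
                 dup_mutation_rate = dup_mutation_rate,
                 seed = as.integer(seed)),
            class = "sca_planted_spec")
}

#' Generate a planted-sector synthetic alignment
#'
#' Non-sector positions are drawn i.i.d. from a position-specific
#' distribution: near-invariant positions show a preferred residue with
#' probability `invariant_strength` (background draw otherwise), neutral
#' positions draw from the background. For each sector, every sequence
#' draws a latent Bernoulli state; when the state is on, each sector
#' position shows its preferred residue with probability `rho` and a
#' background draw otherwise, yielding correlated conservation across
#' the sector. Subfamily swap maps replace the preferred residue on the
#' stated positions. Duplicates are appended after the core alignment
#' and mutated at the stated rate. Fully reproducible under the spec
#' seed.
#'
#' @param spec an [planted_spec()].
#' @return list with `msa` (an `sca_msa`) and `truth` (class
#'   `sca_truth`): `spec`, `subfamily` (per-sequence labels, duplicates
#'   inherit their parent's), `sector_of_position` (integer or `NA` per
#'   position), `latent` (M x n_sectors matrix of latent states for the
#'   core sequences).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sca_planted_spec"))
  withr_seed(spec$seed, {
    M <- spec$M; L <- spec$L; q <- spec$q
    sector_pos <- unlist(lapply(spec$sectors, `[[`, "positions"))
    nonsector <- setdiff(seq_len(L), sector_pos)
    n_inv <- round(spec$frac_invariant * length(nonsector))
    invariant <- if (n_inv > 0) sort(sample(nonsector, n_inv)) else integer(0)
    neutral <- setdiff(nonsector, invariant)

    draw_bg <- function(n) sample.int(20L, n, replace = TRUE, prob = q)
    A <- matrix(0L, M, L)
    for (i in neutral) A[, i] <- draw_bg(M)
    inv_pref <- stats::setNames(draw_bg(length(invariant)),
                                as.character(invariant))
    for (i in invariant) {
      show <- stats::runif(M) < spec$invariant_strength
      A[, i] <- ifelse(show, inv_pref[[as.character(i)]], draw_bg(M))
    }

    ## subfamily assignment of core sequences
    if (!is.null(spec$subfamilies)) {
      fr <- vapply(spec$subfamilies, `[[`, numeric(1), "fraction")
      sizes <- diff(round(cumsum(c(0, fr)) * M))
      subfam <- sample(rep.int(seq_along(fr), sizes))
    } else {
      subfam <- rep(1L, M)
    }

    ## planted sectors: latent on/off state per sequence and sector
    latent <- matrix(FALSE, M, length(spec$sectors))
    for (k in seq_along(spec$sectors)) {
      sec <- spec$sectors[[k]]
      p_on <- if (is.null(sec$p_on)) 0.5 else sec$p_on
      pref <- sec$preferred
      if (is.null(pref)) pref <- draw_bg(length(sec$positions))
      latent[, k] <- stats::runif(M) < p_on
      for (jj in seq_along(sec$positions)) {
        i <- sec$positions[jj]
        pref_i <- rep(pref[jj], M)
        ## subfamily swap maps override the preferred residue
        if (!is.null(spec$subfamilies)) {
          for (sf in seq_along(spec$subfamilies)) {
            sw <- spec$subfamilies[[sf]]
            if (i %in% sw$swap_positions) {
              to <- sw$swap_to
              if (is.null(to)) to <- (pref[jj] %% 20L) + sf - 1L
              to <- ((to - 1L) %% 20L) + 1L
              pref_i[subfam == sf] <- to[((match(i, sw$swap_positions) - 1L)
                                          %% length(to)) + 1L]
            }
          }
        }
        show <- latent[, k] & stats::runif(M) < sec$rho
        A[, i] <- ifelse(show, pref_i, draw_bg(M))
      }
    }

    ## redundancy: mutated duplicate copies appended after the core
    n_dup_each <- round(spec$dup_factor) - 1L
    if (n_dup_each > 0) {
      parents <- rep(seq_len(M), each = n_dup_each)
      D <- A[parents, , drop = FALSE]
      if (spec$dup_mutation_rate > 0) {
        mut <- which(matrix(stats::runif(length(D)) <
                              spec$dup_mutation_rate, nrow(D)))
        D[mut] <- sample.int(20L, length(mut), replace = TRUE, prob = q)
      }
      A <- rbind(A, D)
      subfam_all <- c(subfam, subfam[parents])
    } else {
      subfam_all <- subfam
    }

    sector_of_position <- rep(NA_integer_, L)
    for (k in seq_along(spec$sectors))
      sector_of_position[spec$sectors[[k]]$positions] <- k

    ids <- sprintf("seq%05d", seq_len(nrow(A)))
    msa <- new_msa(ids, decode_rows(A))
    truth <- structure(list(spec = spec,
                            subfamily = subfam_all,
                            sector_of_position = sector_of_position,
                            latent = latent),
                       class = "sca_truth")
    list(msa = msa, truth = truth)
  })
}

#' Serialize ground truth as JSON
#' @param truth an `sca_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  spec <- truth$spec
  payload <- list(
    spec = list(M = spec$M, L = spec$L, frac_invariant = spec$frac_invariant,
                invariant_strength = spec$invariant_strength,
                sectors = lapply(spec$sectors, function(s)
                  list(positions = s$positions, rho = s$rho)),
                dup_factor = spec$dup_factor,
                dup_mutation_rate = spec$dup_mutation_rate,
                seed = spec$seed),
    subfamily = truth$subfamily,
    sector_of_position = truth$sector_of_position)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}
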