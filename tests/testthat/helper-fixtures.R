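## Shared fixtures; everything is generated in code, nothing is stored.

toy_msa <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  new_msa(ids, rows)
}

write_fasta_tmp <- function(rows, ids = sprintf("s%d", seq_along(rows)),
                            desc = rep("", length(rows))) {
  f <- tempfile(fileext = ".fasta")
  hdr <- ifelse(nzchar(desc), paste0(">", ids, " ", desc), paste0(">", ids))
  writeLines(as.vector(rbind(hdr, rows)), f)
  f
}

## minimal processed-alignment wrapper with explicit weights, bypassing
## the filtering pipeline (used where a test needs exact unit weights)
fake_processed <- function(msa, w = rep(1, msa$M), lambda = 0.03) {
  structure(list(msa = msa,
                 weights = structure(list(w = w, M_eff = sum(w)),
                                     class = "sca_weights"),
                 position_map = NULL,
                 params = preprocess_params(lambda = lambda),
                 column_mask = rep(TRUE, msa$L),
                 provenance = list()),
            class = "sca_processed")
}

## permissive parameters: nothing is filtered
permissive_params <- function(lambda = 0.03, ...) {
  preprocess_params(pos_gap_cutoff = 1, seq_gap_cutoff = 1,
                    min_ref_identity = 0, weighted_pos_gap_cutoff = 1,
                    lambda = lambda, ...)
}

## memoized expensive fixtures (shared across test files)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## standard planted two-sector world (the acceptance world)
planted2_spec <- function(seed) planted_spec(seed = seed)

## hierarchy world: one 16-position sector split 8/8 across two
## subfamilies plus an independent 10-position sector
hierarchy_spec <- function(seed) {
  planted_spec(seed = seed, frac_invariant = 0,
    sectors = list(list(positions = 1:16, rho = 0.9,
                        preferred = rep(4L, 16)),
                   list(positions = 17:26, rho = 0.9,
                        preferred = rep(10L, 10))),
    subfamilies = list(list(fraction = 0.5, swap_positions = integer(0)),
                       list(fraction = 0.5, swap_positions = 1:8,
                            swap_to = rep(16L, 8))))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
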