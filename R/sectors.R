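## Maximum-likelihood location-scale t fit with df >= 1.
## Returns list(m, s, df, ok).
.fit_t <- function(x) {
  if (stats::sd(x) < .Machine$double.eps^0.5)
    return(list(m = mean(x), s = NA_real_, df = NA_real_, ok = FALSE))
  nll <- function(par) {
    m <- par[1L]; s <- exp(par[2L]); df <- 1 + exp(par[3L])
    -sum(stats::dt((x - m) / s, df = df, log = TRUE) - log(s))
  }
  start <- c(stats::median(x), log(max(stats::mad(x), 1e-3)), log(4))
  fit <- tryCatch(stats::optim(start, nll, method = "Nelder-Mead",
                               control = list(maxit = 2000)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value))
    return(list(m = NA_real_, s = NA_real_, df = NA_real_, ok = FALSE))
  list(m = fit$par[1L], s = exp(fit$par[2L]), df = 1 + exp(fit$par[3L]),
       ok = TRUE)
}

#' Select top positions of an independent component
#'
#' Fits a location-scale t distribution to the IC loadings by maximum
#' likelihood (df bounded at 1) and selects the positions whose fitted
#' CDF exceeds `cdf_cutoff` on the positive (sign-oriented) tail. On fit
#' failure the empirical `cdf_cutoff` quantile is used instead, with a
#' logged warning. Selected positions are ordered by descending
#' absolute loading.
#'
#' @param ic_loadings numeric vector of length L (a sign-oriented IC).
#' @param cdf_cutoff CDF cutoff (default 0.95); 1.0 selects nothing.
#' @param ic_index integer label carried through to the output.
#' @param labels optional character position labels (length L).
#' @return list of class `sca_ic_positions`: `ic_index`, `positions`
#'   (1-based column indices, ordered), `labels`, `loadings`, `fit`
#'   (m, s, df, ok), `cdf_cutoff`, `fallback` (logical).
#' @export
fit_ic_and_select <- function(ic_loadings, cdf_cutoff = 0.95,
                              ic_index = 1L, labels = NULL) {
  L <- length(ic_loadings)
  if (L < 10L) stop("at least 10 loadings required for a distribution fit")
  if (cdf_cutoff < 0 || cdf_cutoff > 1) stop("cdf_cutoff must be in [0, 1]")
  fit <- .fit_t(ic_loadings)
  fallback <- !fit$ok
  if (fit$ok) {
    cdf <- stats::pt((ic_loadings - fit$m) / fit$s, df = fit$df)
    sel <- which(cdf > cdf_cutoff)
  } else {
    warning("t fit failed for IC ", ic_index,
            "; falling back to the empirical quantile cutoff")
    if (stats::sd(ic_loadings) < .Machine$double.eps^0.5 ||
        cdf_cutoff >= 1) {
      sel <- integer(0)
    } else {
      thr <- stats::quantile(ic_loadings, cdf_cutoff, names = FALSE)
      sel <- which(ic_loadings > thr)
    }
  }
  sel <- sel[order(-abs(ic_loadings[sel]))]
  if (is.null(labels)) labels <- as.character(seq_len(L))
  structure(list(ic_index = as.integer(ic_index), positions = sel,
                 labels = labels[sel], loadings = ic_loadings[sel],
                 fit = fit, cdf_cutoff = cdf_cutoff, fallback = fallback),
            class = "sca_ic_positions")
}

#' Resolve positions selected by several ICs
#'
#' A position passing the cutoff on multiple ICs is assigned to the IC
#' where its absolute loading is largest; ties go to the lower IC index.
#'
#' @param sets list of `sca_ic_positions`.
#' @return the same list with overlaps removed (ordering preserved).
#' @export
resolve_overlaps <- function(sets) {
  all_pos <- unlist(lapply(sets, `[[`, "positions"))
  dup <- unique(all_pos[duplicated(all_pos)])
  if (!length(dup)) return(sets)
  for (p in dup) {
    claims <- vapply(sets, function(s) {
      i <- match(p, s$positions)
      if (is.na(i)) -Inf else abs(s$loadings[i])
    }, numeric(1))
    winner <- which.max(claims)   # which.max takes the first (lowest IC) tie
    for (k in seq_along(sets)) {
      if (k == winner) next
      i <- match(p, sets[[k]]$positions)
      if (!is.na(i)) {
        sets[[k]]$positions <- sets[[k]]$positions[-i]
        sets[[k]]$labels <- sets[[k]]$labels[-i]
        sets[[k]]$loadings <- sets[[k]]$loadings[-i]
      }
    }
  }
  sets
}

#' IC-ordered submatrix of the coevolution matrix
#'
#' Rows and columns are the selected positions, ordered IC by IC and
#' within an IC by descending loading; entries are copied from `Cpos`.
#'
#' @param Cpos L x L positional coevolution matrix.
#' @param sets disjoint list of `sca_ic_positions` (see
#'   [resolve_overlaps()]).
#' @return list of class `sca_sector_model`: `submatrix`, `blocks`
#'   (per-IC index ranges into the submatrix), `sets`; `inter_ic_stats`
#'   and `sector_assignments` unset until [inter_ic_coupling()] /
#'   [group_ics()].
#' @export
build_submatrix <- function(Cpos, sets) {
  sizes <- vapply(sets, function(s) length(s$positions), integer(1))
  if (sum(sizes) == 0L) stop("empty position-set union")
  idx <- unlist(lapply(sets, `[[`, "positions"))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- Map(function(a, b) if (b >= a) a:b else integer(0),
                starts, ends)
  structure(list(submatrix = Cpos[idx, idx, drop = FALSE],
                 blocks = blocks, sets = sets,
                 inter_ic_stats = NULL, sector_assignments = NULL,
                 mode = NULL),
            class = "sca_sector_model")
}

#' Between-IC coupling statistics
#'
#' For groups g, h the statistic is the mean of the off-diagonal block
#' of the submatrix between g and h, normalized by the geometric mean of
#' the within-group means (mean off-diagonal entries of each diagonal
#' block; a singleton group falls back to its diagonal entry, flagged).
#' The diagonal of the statistic matrix is 1.
#'
#' @param model an `sca_sector_model`.
#' @return the model with `inter_ic_stats` (k x k matrix) filled in.
#' @export
inter_ic_coupling <- function(model) {
  blocks <- model$blocks
  k <- length(blocks)
  if (k < 2L) stop("at least 2 ICs required")
  S <- model$submatrix
  within <- vapply(seq_len(k), function(g) {
    b <- blocks[[g]]
    if (length(b) == 0L) return(NA_real_)
    if (length(b) == 1L) {
      message("singleton IC group ", g, ": using its diagonal entry")
      return(S[b, b])
    }
    B <- S[b, b, drop = FALSE]
    mean(B[row(B) != col(B)])
  }, numeric(1))
  stats <- diag(1, k)
  for (g in seq_len(k - 1L)) for (h in (g + 1L):k) {
    bg <- blocks[[g]]; bh <- blocks[[h]]
    if (!length(bg) || !length(bh)) { stats[g, h] <- stats[h, g] <- NA; next }
    off <- mean(S[bg, bh, drop = FALSE])
    stats[g, h] <- stats[h, g] <- off / sqrt(within[g] * within[h])
  }
  model$inter_ic_stats <- stats
  model
}

#' Group ICs into sectors
#'
#' Auto mode links IC pairs whose coupling statistic exceeds
#' `threshold` and takes connected components (transitive grouping);
#' manual mode applies a user partition verbatim.
#'
#' @param model an `sca_sector_model` with `inter_ic_stats`.
#' @param threshold coupling threshold for auto grouping (default 0.25).
#' @param manual optional list of integer vectors partitioning
#'   `1..k`.
#' @return the model with `sector_assignments` (list of integer vectors)
#'   and `mode` filled in.
#' @export
group_ics <- function(model, threshold = 0.25, manual = NULL) {
  k <- length(model$blocks)
  if (!is.null(manual)) {
    flat <- sort(unlist(manual))
    if (!identical(as.integer(flat), seq_len(k)))
      stop("manual grouping must partition 1..", k)
    model$sector_assignments <- lapply(manual, as.integer)
    model$mode <- "manual"
    return(model)
  }
  stats <- model$inter_ic_stats
  if (is.null(stats)) stop("run inter_ic_coupling() first")
  ## connected components of the thresholded coupling graph
  comp <- seq_len(k)
  for (g in seq_len(k - 1L)) for (h in (g + 1L):k) {
    if (!is.na(stats[g, h]) && stats[g, h] > threshold) {
      old <- comp[h]; comp[comp == old] <- comp[g]
    }
  }
  model$sector_assignments <- unname(split(seq_len(k), match(comp,
                                                             unique(comp))))
  model$mode <- "auto"
  model
}

#' Define sectors from a decomposition
#'
#' Convenience wrapper: per-IC position selection, overlap resolution,
#' submatrix construction, inter-IC coupling and (for k >= 2) automatic
#' grouping.
#'
#' @param Cpos L x L positional coevolution matrix.
#' @param decomposition an `sca_decomposition` with `k_star >= 1`.
#' @param cdf_cutoff CDF cutoff for position selection (default 0.95).
#' @param threshold auto-grouping coupling threshold (default 0.25).
#' @param manual optional manual partition of the ICs.
#' @param labels optional position labels (length L).
#' @return an `sca_sector_model` with `sector_assignments` set; sector
#'   `positions` are available through [sector_positions()].
#' @export
define_sectors <- function(Cpos, decomposition, cdf_cutoff = 0.95,
                           threshold = 0.25, manual = NULL, labels = NULL) {
  if (decomposition$k_star < 1L) stop("no significant eigenmodes")
  ICs <- decomposition$ica$ICs
  sets <- lapply(seq_len(ncol(ICs)), function(p)
    fit_ic_and_select(ICs[, p], cdf_cutoff, ic_index = p, labels = labels))
  sets <- resolve_overlaps(sets)
  nonempty <- vapply(sets, function(s) length(s$positions) > 0L, logical(1))
  if (!any(nonempty)) stop("no positions selected on any IC")
  model <- build_submatrix(Cpos, sets)
  if (sum(nonempty) >= 2L) {
    model <- inter_ic_coupling(model)
    model <- group_ics(model, threshold, manual)
  } else {
    model$sector_assignments <- list(which(nonempty))
    model$mode <- if (is.null(manual)) "auto" else "manual"
  }
  model
}

#' Per-sector position lists
#'
#' @param model an `sca_sector_model` with `sector_assignments`.
#' @return list (one element per sector) of data.frames with columns
#'   `ic`, `position` (1-based column index), `label`, `loading`.
#' @export
sector_positions <- function(model) {
  lapply(model$sector_assignments, function(ics) {
    do.call(rbind, lapply(ics, function(p) {
      s <- model$sets[[p]]
      if (!length(s$positions)) return(NULL)
      data.frame(ic = p, position = s$positions, label = s$labels,
                 loading = s$loadings, stringsAsFactors = FALSE)
    }))
  })
}
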