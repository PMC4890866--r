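#' Map positional eigenmodes and ICs into sequence space
#'
#' Projects every sequence onto the retained eigenmodes of the
#' positional coevolution matrix through the reduced alignment,
#' `U = x V diag(1/sqrt(lambda))`, and onto the independent components,
#' `Up = U W^T`. Modes with non-positive eigenvalue are excluded with a
#' warning.
#'
#' @param x reduced alignment (M x L), e.g. from
#'   [projection_and_reduce()].
#' @param spectrum an `sca_spectrum`.
#' @param ica an `sca_ica` (or `NULL` to skip the IC rotation).
#' @param k number of modes to map (default: `ncol(ica$W)`, else all
#'   positive-eigenvalue modes).
#' @return list of class `sca_seqspace`: `U` (M x k), `Up` (M x k or
#'   `NULL`), `modes` (indices of mapped modes).
#' @export
sequence_projection <- function(x, spectrum, ica = NULL, k = NULL) {
  if (is.null(k)) k <- if (!is.null(ica)) ncol(ica$W) else
    sum(spectrum$values > 0)
  modes <- seq_len(k)
  bad <- modes[spectrum$values[modes] <= 0]
  if (length(bad)) {
    warning("excluding mode(s) with non-positive eigenvalue: ",
            paste(bad, collapse = ", "))
    modes <- setdiff(modes, bad)
  }
  if (!length(modes)) stop("no modes with positive eigenvalue to map")
  V <- spectrum$vectors[, modes, drop = FALSE]
  lam <- spectrum$values[modes]
  U <- x %*% V %*% diag(1 / sqrt(lam), nrow = length(lam))
  Up <- NULL
  if (!is.null(ica)) {
    if (!identical(modes, seq_len(ncol(ica$W))))
      stop("ICA modes and mapped modes disagree")
    Up <- U %*% t(ica$W)
  }
  structure(list(U = U, Up = Up, modes = modes), class = "sca_seqspace")
}

## rank-biserial correlation of one class vs the rest along a coordinate
.rank_biserial <- function(coord, is_class) {
  n1 <- sum(is_class); n2 <- sum(!is_class)
  if (n1 == 0L || n2 == 0L) return(0)
  r <- rank(coord)
  ustat <- sum(r[is_class]) - n1 * (n1 + 1) / 2
  2 * ustat / (n1 * n2) - 1
}

#' Annotation structure along each independent component
#'
#' For every mapped IC coordinate, builds per-class histograms (fixed
#' shared binning, recorded in the output) and a class-separation score:
#' the rank-biserial correlation of each class against the rest.
#'
#' @param seqspace an `sca_seqspace` with non-`NULL` `Up`.
#' @param labels character vector of per-sequence class labels (MSA
#'   order), e.g. a column of [join_annotations()].
#' @param n_bins number of histogram bins (default 30).
#' @return list of class `sca_mode_annotation`: `histograms` (list per
#'   IC: `breaks` + class count matrix), `separation` (classes x ICs
#'   matrix of rank-biserial scores).
#' @export
annotate_modes <- function(seqspace, labels, n_bins = 30L) {
  Up <- seqspace$Up
  if (is.null(Up)) stop("sequence space has no IC coordinates")
  labels <- as.character(labels)
  if (length(labels) != nrow(Up))
    stop("one label per sequence required")
  classes <- sort(unique(labels))
  if (length(classes) < 1L) stop("empty annotation join")
  k <- ncol(Up)
  histograms <- vector("list", k)
  separation <- matrix(0, length(classes), k,
                       dimnames = list(classes, paste0("IC", seq_len(k))))
  for (p in seq_len(k)) {
    coord <- Up[, p]
    breaks <- seq(min(coord), max(coord), length.out = n_bins + 1L)
    if (breaks[1L] == breaks[n_bins + 1L])
      breaks <- breaks[1L] + seq(-0.5, 0.5, length.out = n_bins + 1L)
    counts <- vapply(classes, function(cl)
      graphics::hist(coord[labels == cl], breaks = breaks,
                     plot = FALSE)$counts, numeric(n_bins))
    histograms[[p]] <- list(breaks = breaks, counts = t(counts))
    if (length(classes) > 1L)
      separation[, p] <- vapply(classes, function(cl)
        .rank_biserial(coord, labels == cl), numeric(1))
  }
  structure(list(histograms = histograms, separation = separation),
            class = "sca_mode_annotation")
}
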