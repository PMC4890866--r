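#' Assemble a run configuration
#'
#' One document holding every stage parameter; unknown keys are
#' rejected and the effective (defaults-merged) configuration is echoed
#' into every results bundle.
#'
#' @param ... overrides for: `pos_gap_cutoff`, `seq_gap_cutoff`,
#'   `min_ref_identity`, `weight_identity_threshold`,
#'   `weighted_pos_gap_cutoff`, `lambda`, `resample`, `resample_factor`,
#'   `norm_kind`, `n_trials`, `cdf_cutoff`, `group_threshold`,
#'   `reference_id`, `labels`, `seed`.
#' @return list of class `sca_config`.
#' @export
sca_config <- function(...) {
  defaults <- list(pos_gap_cutoff = 0.4, seq_gap_cutoff = 0.2,
                   min_ref_identity = 0.2, weight_identity_threshold = 0.8,
                   weighted_pos_gap_cutoff = 0.2, lambda = 0.03,
                   resample = FALSE, resample_factor = 1.5,
                   norm_kind = "frobenius", n_trials = 10L,
                   cdf_cutoff = 0.95, group_threshold = 0.25,
                   reference_id = NULL, labels = NULL, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "sca_config")
}

#' Run the full sector analysis
#'
#' Orchestrates preprocessing, coevolution, decomposition (spectrum,
#' randomization null, k*, ICA), sequence-space mapping and sector
#' identification on one alignment, returning a single results bundle.
#' A pure-noise alignment (`k* = 0`) terminates cleanly with status
#' `"no significant eigenmodes"` and `sectors = NULL`.
#'
#' @param msa an `sca_msa`, or a file path readable by
#'   [read_alignment()].
#' @param config an [sca_config()].
#' @param format alignment format when `msa` is a path.
#' @return list of class `sca_result`: `config`, `processed`, `coevo`,
#'   `decomposition`, `seqspace`, `sectors`, `summary` (list with
#'   `status`, `M`, `L`, `M_eff`, `k_star`, `n_sectors`,
#'   `sector_sizes`).
#' @export
run_sca <- function(msa, config = sca_config(), format = "fasta") {
  if (is.character(msa)) msa <- read_alignment(msa, format)
  params <- preprocess_params(
    pos_gap_cutoff = config$pos_gap_cutoff,
    seq_gap_cutoff = config$seq_gap_cutoff,
    min_ref_identity = config$min_ref_identity,
    weight_identity_threshold = config$weight_identity_threshold,
    weighted_pos_gap_cutoff = config$weighted_pos_gap_cutoff,
    lambda = config$lambda, resample = config$resample,
    resample_factor = config$resample_factor, seed = config$seed)
  processed <- preprocess(msa, params, config$reference_id, config$labels)
  coevo <- coevolution_matrix(processed, norm_kind = config$norm_kind)
  decomp <- decompose(coevo, processed, n_trials = config$n_trials,
                      seed = config$seed)
  labels <- position_labels(processed)
  if (decomp$k_star == 0L) {
    message("no significant eigenmodes; stopping before sector analysis")
    summary <- list(status = "no significant eigenmodes",
                    M = processed$msa$M, L = processed$msa$L,
                    M_eff = processed$weights$M_eff, k_star = 0L,
                    n_sectors = 0L, sector_sizes = integer(0))
    return(structure(list(config = config, processed = processed,
                          coevo = coevo, decomposition = decomp,
                          seqspace = NULL, sectors = NULL,
                          summary = summary), class = "sca_result"))
  }
  seqspace <- sequence_projection(coevo$projection$x, decomp$spectrum,
                                  decomp$ica)
  sectors <- define_sectors(coevo$Cpos, decomp,
                            cdf_cutoff = config$cdf_cutoff,
                            threshold = config$group_threshold,
                            labels = labels)
  sizes <- vapply(sector_positions(sectors), function(d)
    if (is.null(d)) 0L else nrow(d), integer(1))
  summary <- list(status = "ok", M = processed$msa$M, L = processed$msa$L,
                  M_eff = processed$weights$M_eff,
                  k_star = decomp$k_star,
                  n_sectors = length(sectors$sector_assignments),
                  sector_sizes = sizes)
  structure(list(config = config, processed = processed, coevo = coevo,
                 decomposition = decomp, seqspace = seqspace,
                 sectors = sectors, summary = summary),
            class = "sca_result")
}

#' @export
print.sca_result <- function(x, ...) {
  s <- x$summary
  cat("<sca_result> ", s$M, " x ", s$L, " (M_eff = ",
      round(s$M_eff, 1), "); k* = ", s$k_star, "; ", s$n_sectors,
      " sector(s)\n", sep = "")
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' Emits the processed alignment (FASTA), weights CSV, position-map
#' CSV, conservation CSV, positional coevolution matrix TSV, spectrum
#' and null-spectrum CSV, IC loadings TSV, per-sequence coordinates
#' CSV, per-IC position CSV, sector CSV, submatrix TSV, and a summary
#' JSON echoing the effective configuration and provenance.
#'
#' @param result an `sca_result`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  pr <- result$processed
  write_alignment(pr$msa, p("processed.fasta"))
  utils::write.csv(data.frame(id = pr$msa$ids, weight = pr$weights$w),
                   p("weights.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(pr$position_map)) write_position_map(pr$position_map,
                                                    p("position_map.csv"))
  labels <- position_labels(pr)
  cons <- result$coevo$conservation
  top <- AA_ALPHABET[apply(result$coevo$freqs$f1[, -1L, drop = FALSE],
                           1L, which.max)]
  utils::write.csv(data.frame(position = labels, Di = cons$Di,
                              top_residue = top),
                   p("conservation.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(result$coevo$Cpos, p("coevolution_matrix.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  de <- result$decomposition
  utils::write.csv(data.frame(mode = seq_along(de$spectrum$values),
                              eigenvalue = de$spectrum$values),
                   p("spectrum.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(rank = seq_len(ncol(de$null_values)),
                              mean = colMeans(de$null_values),
                              sd = apply(de$null_values, 2L, stats::sd)),
                   p("null_spectrum.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(de$ica))
    utils::write.table(de$ica$ICs, p("ic_loadings.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(result$seqspace)) {
    co <- as.data.frame(result$seqspace$Up)
    names(co) <- paste0("IC", seq_len(ncol(co)))
    utils::write.csv(cbind(data.frame(id = pr$msa$ids), co),
                     p("sequence_coordinates.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(result$sectors)) {
    secs <- sector_positions(result$sectors)
    tab <- do.call(rbind, Map(function(d, s)
      if (is.null(d)) NULL else cbind(sector = s, d),
      secs, seq_along(secs)))
    utils::write.csv(tab, p("sectors.csv"), row.names = FALSE, quote = FALSE)
    utils::write.table(result$sectors$submatrix, p("sector_submatrix.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    writeLines(vapply(seq_along(secs), function(s)
      paste0("sector", s, ": ",
             paste(secs[[s]]$label, collapse = " ")), character(1)),
      p("sector_residues.txt"))
  }
  meta <- list(package_version = as.character(utils::packageVersion("protsca")),
               config = result$config[!vapply(result$config, is.null,
                                              logical(1))],
               provenance = pr$provenance,
               summary = result$summary)
  jsonlite::write_json(meta, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(outdir)
}
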