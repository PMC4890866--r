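#' Multiple sequence alignment container
#'
#' A light S3 container for an aligned set of protein sequences. Rows are
#' stored both as character strings (`rows`) and as an integer code matrix
#' (`codes`, 0 = gap, 1..20 = amino acid in [AA_ALPHABET]).
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of aligned rows (equal lengths).
#' @param descriptions optional character vector of free-text descriptions.
#' @return an object of class `sca_msa` with elements `ids`, `descriptions`,
#'   `rows`, `codes`, `M` (sequences) and `L` (columns).
#' @export
new_msa <- function(ids, rows, descriptions = NULL) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop("ids and rows must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment error: ragged rows (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  if (lens[1L] < 1L) stop("alignment error: zero-length rows")
  if (is.null(descriptions)) descriptions <- rep("", length(ids))

  ## normalize: '.' and non-canonical residues -> gap (logged)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  n_bad <- sum(vapply(NONCANONICAL, function(ch)
    sum(lengths(regmatches(rows, gregexpr(ch, rows, fixed = TRUE)))),
    numeric(1)))
  if (n_bad > 0) {
    for (ch in NONCANONICAL) rows <- gsub(ch, "-", rows, fixed = TRUE)
    message("normalized ", n_bad, " non-canonical residue(s) to gap")
  }
  codes <- encode_rows(rows)
  ## anything still unrecognized (digits, etc.) became 0; rewrite rows from
  ## codes so rows and codes always agree
  rows <- decode_rows(codes)
  structure(list(ids = ids, descriptions = descriptions, rows = rows,
                 codes = codes, M = length(ids), L = ncol(codes)),
            class = "sca_msa")
}

#' @export
print.sca_msa <- function(x, ...) {
  cat("<sca_msa> ", x$M, " sequences x ", x$L, " positions\n", sep = "")
  invisible(x)
}

#' Subset an alignment by sequences and/or columns
#' @param msa an `sca_msa`.
#' @param seqs integer/logical index of sequences to keep.
#' @param cols integer/logical index of columns to keep.
#' @return an `sca_msa`.
#' @export
msa_subset <- function(msa, seqs = NULL, cols = NULL) {
  codes <- msa$codes
  ids <- msa$ids; desc <- msa$descriptions
  if (!is.null(seqs)) {
    codes <- codes[seqs, , drop = FALSE]
    ids <- ids[seqs]; desc <- desc[seqs]
  }
  if (!is.null(cols)) codes <- codes[, cols, drop = FALSE]
  new_msa(ids, decode_rows(codes), desc)
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm 1.0 file. Rows are upper-cased,
#' '.' and non-canonical residues (B, Z, X, U, O, J, *) are normalized to
#' gap with a logged count. For Stockholm input, `#=GS` annotation lines
#' are harvested into an annotation table attached as attribute
#' `"annotations"`.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return an [new_msa()] object; Stockholm input additionally carries an
#'   `annotations` attribute (data.frame id/feature/value).
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e)
                      stop("format error reading FASTA '", path, "': ",
                           conditionMessage(e)))
    if (length(set) == 0L) stop("format error: no records in ", path)
    full <- names(set)
    ids <- sub("\\s.*$", "", full)
    desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
    new_msa(ids, as.character(set), desc)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L]))
      stop("format error: missing '# STOCKHOLM' header in ", path)
    seq_lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                         nzchar(trimws(lines))]
    if (!length(seq_lines)) stop("format error: no sequence lines in ", path)
    parts <- regmatches(seq_lines, regexpr("^\\S+", seq_lines))
    seqs <- trimws(sub("^\\S+\\s+", "", seq_lines))
    ## interleaved blocks: concatenate per id in first-appearance order
    agg <- tapply(seqs, factor(parts, levels = unique(parts)), paste,
                  collapse = "")
    msa <- new_msa(names(agg), unname(agg))
    gs <- lines[grepl("^#=GS\\s", lines)]
    ann <- NULL
    if (length(gs)) {
      m <- regmatches(gs, regexec("^#=GS\\s+(\\S+)\\s+(\\S+)\\s+(.*)$", gs))
      ok <- lengths(m) == 4L
      if (any(ok)) {
        ann <- data.frame(id = vapply(m[ok], `[`, "", 2L),
                          feature = vapply(m[ok], `[`, "", 3L),
                          value = vapply(m[ok], `[`, "", 4L),
                          stringsAsFactors = FALSE)
      }
    }
    attr(msa, "annotations") <- ann
    msa
  }
}

#' Write an alignment as canonical FASTA
#'
#' One header line (`>id description`, description omitted when empty) and
#' one sequence line per record; `write_alignment(read_alignment(f))`
#' reproduces such a file byte-for-byte.
#'
#' @param msa an `sca_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  hdr <- ifelse(nzchar(msa$descriptions),
                paste0(">", msa$ids, " ", msa$descriptions),
                paste0(">", msa$ids))
  writeLines(as.vector(rbind(hdr, msa$rows)), path)
  invisible(path)
}

#' Parse a per-sequence annotation table
#'
#' @param path delimited text file (TSV or CSV, sniffed from the header
#'   line) with one row per sequence.
#' @param id_column name of the column holding sequence ids.
#' @return data.frame keyed by `id` (first column), class
#'   `sca_annotations`; missing cells become empty strings.
#' @export
parse_annotations <- function(path, id_column = "id") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           na.strings = character(0))
  if (!id_column %in% names(tab))
    stop("id column '", id_column, "' not found in header: ",
         paste(names(tab), collapse = ", "))
  ids <- as.character(tab[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate ids in annotation table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tab[] <- lapply(tab, function(col) {
    col <- as.character(col); col[is.na(col)] <- ""; col
  })
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
               tab[setdiff(names(tab), id_column)])
  class(out) <- c("sca_annotations", "data.frame")
  out
}

#' Join annotations onto an alignment
#'
#' Unmatched annotation ids are retained in the table but logged; MSA
#' sequences without annotation get empty labels.
#'
#' @param msa an `sca_msa`.
#' @param annotations result of [parse_annotations()].
#' @return data.frame with one row per MSA sequence, in MSA order.
#' @export
join_annotations <- function(msa, annotations) {
  unmatched <- setdiff(annotations$id, msa$ids)
  if (length(unmatched))
    message(length(unmatched),
            " annotated id(s) absent from the alignment (kept in table)")
  idx <- match(msa$ids, annotations$id)
  out <- annotations[idx, , drop = FALSE]
  out$id <- msa$ids
  out[] <- lapply(out, function(col) { col[is.na(col)] <- ""; col })
  rownames(out) <- NULL
  out
}

#' Map alignment columns to reference-sequence numbering
#'
#' Columns where the reference sequence is ungapped are labeled by the
#' 1-based index of the residue in the ungapped reference (or by
#' user-supplied labels, e.g. structure numbering); columns where the
#' reference is gapped carry `NA` and are flagged.
#'
#' @param msa an `sca_msa`.
#' @param reference_id id of the reference sequence.
#' @param labels optional character vector, one label per ungapped
#'   reference residue.
#' @return data.frame of class `sca_position_map` with columns
#'   `column_index` (0-based), `reference_label` (character or `NA`) and
#'   `mapped` (logical).
#' @export
build_position_map <- function(msa, reference_id, labels = NULL) {
  ri <- match(reference_id, msa$ids)
  if (is.na(ri)) stop("unknown reference_id: ", reference_id)
  refcodes <- msa$codes[ri, ]
  ungapped <- refcodes != 0L
  n_ref <- sum(ungapped)
  if (n_ref == 0L) stop("degenerate reference: all gaps")
  if (is.null(labels)) labels <- as.character(seq_len(n_ref))
  if (length(labels) != n_ref)
    stop("label count (", length(labels), ") != ungapped reference length (",
         n_ref, ")")
  if (anyDuplicated(labels)) stop("reference labels must be unique")
  lab <- rep(NA_character_, msa$L)
  lab[ungapped] <- labels
  out <- data.frame(column_index = seq_len(msa$L) - 1L,
                    reference_label = lab, mapped = ungapped,
                    stringsAsFactors = FALSE)
  class(out) <- c("sca_position_map", "data.frame")
  out
}

#' Write a position map as two-column CSV
#' @param map an `sca_position_map`.
#' @param path output path.
#' @export
write_position_map <- function(map, path) {
  utils::write.csv(map[, c("column_index", "reference_label")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
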