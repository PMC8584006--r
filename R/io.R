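#' Read a protein FASTA file
#'
#' Reads an amino-acid FASTA file into a named character vector of sequences,
#' one element per record, named by the first whitespace-delimited token of
#' the header. Sequences are uppercased. Records must use the 20 standard
#' amino-acid letters; any other character is a parse error unless
#' `permissive = TRUE`, in which case it is replaced by `"X"`.
#'
#' @param path path to a FASTA file.
#' @param permissive map non-standard residue letters to `"X"` instead of
#'   failing (default `FALSE`).
#' @return named character vector of uppercase protein sequences.
#' @seealso [write_fasta()], [extract_window()]
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop_pf("FASTA file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_pf("duplicate protein id in FASTA: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop_pf("empty sequence for record: %s",
            paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    if (permissive) {
      seqs[bad] <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X",
                        seqs[bad])
    } else {
      stop_pf("non-standard residue letters in record: %s",
              paste(ids[bad], collapse = ", "))
    }
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)))
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Extract the flanking window around a site
#'
#' Returns the `2*flank + 1` residue window centred on `position` (1-based) of
#' `sequence`; positions beyond either terminus are padded with `"_"`, the
#' convention used throughout motif matching (a pad never matches a residue).
#'
#' @param sequence a single protein sequence string.
#' @param position integer vector of 1-based positions within the sequence.
#' @param flank number of residues on each side (default 6, i.e. 13-mers).
#' @return character vector of windows, one per position.
#' @examples
#' extract_window("MKSTYAAAAAAA", 3)  # "____MKSTYAAAA"
#' @export
extract_window <- function(sequence, position, flank = 6L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  n <- nchar(sequence)
  if (any(position < 1L | position > n)) {
    stop_pf("position out of range 1..%d", n)
  }
  padded <- paste0(strrep(PAD_CHAR, flank), sequence, strrep(PAD_CHAR, flank))
  substring(padded, position, position + 2L * flank)
}

#' Construct a site-by-sample quantification table
#'
#' @param intensities numeric matrix, rows = site ids, columns = sample ids;
#'   strictly positive raw-scale intensities.
#' @param design named character vector mapping sample id to condition label.
#' @return an object of class `quant_table` with elements `sites`, `samples`,
#'   `intensities`, `design`.
#' @export
quant_table <- function(intensities, design) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop_pf("intensities must be finite and strictly positive")
  }
  if (!setequal(names(design), colnames(intensities))) {
    stop_pf("design samples do not match intensity columns")
  }
  design <- design[colnames(intensities)]
  structure(list(sites = rownames(intensities),
                 samples = colnames(intensities),
                 intensities = intensities,
                 design = design),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d sites x %d samples (%s)\n",
              length(x$sites), length(x$samples),
              paste(sprintf("%s x%d", names(table(x$design)),
                            as.integer(table(x$design))), collapse = ", ")))
  invisible(x)
}

#' Read a site-level quantification table
#'
#' The table is a TSV with columns `protein_id`, `position`, `residue`,
#' followed by one intensity column per sample. Windows are recomputed from
#' the protein sequences and validated: a row whose claimed residue does not
#' match the sequence is an error in strict mode and is logged and dropped
#' otherwise.
#'
#' @param path path to the site TSV.
#' @param proteins named character vector of sequences (from [read_fasta()]).
#' @param design named character vector sample -> condition, or the path of a
#'   two-column TSV (`sample`, `condition`).
#' @param strict fail on residue mismatches instead of dropping rows.
#' @return list with `sites` (data.frame: site_id, protein_id, position,
#'   residue, window) and `quant` (a [quant_table()]).
#' @export
read_site_table <- function(path, proteins, design, strict = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("protein_id", "position", "residue")
  if (!all(req %in% names(tab))) {
    stop_pf("site table must have columns %s", paste(req, collapse = ", "))
  }
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    d <- utils::read.delim(design, stringsAsFactors = FALSE)
    design <- stats::setNames(d$condition, d$sample)
  }
  sample_cols <- setdiff(names(tab), req)
  if (length(sample_cols) == 0L) stop_pf("site table has no sample columns")

  unknown <- setdiff(unique(tab$protein_id), names(proteins))
  if (length(unknown)) {
    stop_pf("unknown protein_id in site table: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!all(tab$residue %in% STY)) {
    stop_pf("residue column must be one of S, T, Y")
  }

  seq_char <- substring(proteins[tab$protein_id], tab$position, tab$position)
  mism <- seq_char != tab$residue
  if (any(mism)) {
    msg <- sprintf("%d site(s) whose residue does not match the sequence",
                   sum(mism))
    if (strict) stop_pf("site table: %s", msg)
    pf_log("io", "dropping %s", msg)
    tab <- tab[!mism, , drop = FALSE]
  }

  sites <- data.frame(
    site_id = site_id(tab$protein_id, tab$position, tab$residue),
    protein_id = tab$protein_id,
    position = as.integer(tab$position),
    residue = tab$residue,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites$site_id)) {
    stop_pf("duplicate site_id in table: %s",
            paste(unique(sites$site_id[duplicated(sites$site_id)])[1:3],
                  collapse = ", "))
  }
  sites$window <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteins[[sites$protein_id[i]]], sites$position[i])
  }, character(1))

  m <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sites$site_id
  list(sites = sites, quant = quant_table(m, design))
}

#' Write a site table and its design to TSV
#'
#' Inverse of [read_site_table()]: `<path>` receives the site x sample table
#' and `<design_path>` the sample-to-condition map.
#'
#' @param sites site data.frame as returned by [read_site_table()] or the
#'   simulator.
#' @param quant a [quant_table()].
#' @param path output TSV path for the site table.
#' @param design_path output TSV path for the design (default alongside).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, quant, path,
                             design_path = file.path(dirname(path), "design.tsv")) {
  stopifnot(identical(sites$site_id, rownames(quant$intensities)))
  out <- cbind(sites[, c("protein_id", "position", "residue")],
               as.data.frame(quant$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(quant$design), condition = unname(quant$design)),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected protein-protein interaction edge table
#'
#' @param path TSV with two columns of protein ids (header optional names
#'   `protein_a`, `protein_b`).
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
read_ppi <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(tab))) {
    names(tab)[1:2] <- c("protein_a", "protein_b")
  }
  tab[, c("protein_a", "protein_b")]
}

#' Read an annotation (term membership) table
#'
#' Long-format TSV with columns `term_id`, `term_name`, `namespace`,
#' `protein_id`; one row per term-protein membership.
#'
#' @param path TSV path.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("term_id", "term_name", "namespace", "protein_id")
  if (!all(req %in% names(tab))) {
    stop_pf("annotation table must have columns %s", paste(req, collapse = ", "))
  }
  structure(tab[, req], class = c("annotation_table", "data.frame"))
}
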