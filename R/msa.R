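#' Read a multiple sequence alignment from aligned FASTA
#'
#' Rows must all have the same length; `.` gap characters are normalised to
#' `-` and sequences are uppercased. Columns are addressed 1-based
#' throughout the package.
#'
#' @param path Path to an aligned FASTA file.
#' @return An alignment tibble with columns `id` and `aligned`.
#' @export
read_msa <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort("Alignment file contains no sequences.")
  ids <- stringr::str_split_fixed(names(seqs), "\\s+", 2)[, 1]
  new_alignment(ids, toupper(as.character(seqs)))
}

new_alignment <- function(ids, rows) {
  rows <- stringr::str_replace_all(rows, stringr::fixed("."), GAP)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) {
    ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- ids[lens != ref]
    abort(paste0("Ragged alignment: row(s) ", paste(bad, collapse = ", "),
                 " differ in length."))
  }
  if (lens[1] == 0) abort("Alignment has zero columns.")
  if (anyDuplicated(ids)) abort("Alignment row ids must be unique.")
  tibble(id = ids, aligned = unname(rows))
}

#' Write an alignment to aligned FASTA
#'
#' Output is canonical: uppercase residues, `-` gaps, 60-character line
#' wrap — so read/write round-trips are byte-stable for canonical input.
#'
#' @param aln An alignment tibble (`id`, `aligned`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  seqs <- Biostrings::AAStringSet(setNames(aln$aligned, aln$id))
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Number of columns in an alignment
#' @param aln An alignment tibble.
#' @return Integer column count.
#' @export
n_cols <- function(aln) nchar(aln$aligned[1])

degap <- function(x) stringr::str_remove_all(x, stringr::fixed(GAP))

#' Align a group of sequences with an external aligner
#'
#' Alignment itself is an external, pluggable stage: sequences are written
#' to FASTA, a configurable shell command is run (default MUSCLE with its
#' classic interface), and the resulting aligned FASTA is read back. With
#' `premade_msa` set, the external command is skipped entirely and the
#' pre-computed alignment is read instead (passthrough mode). In either
#' mode the de-gapped alignment rows must reproduce the input sequences;
#' this is checked and violated rows raise an error.
#'
#' @param records A record tibble (see [read_uniprot_fasta()]); row ids in
#'   the alignment are the accessions. Ignored (except for the de-gapping
#'   check) when `premade_msa` is given and `records` is NULL.
#' @param command Command template with `{in}` and `{out}` placeholders,
#'   e.g. `"muscle -in {in} -out {out}"` or `"mafft {in} > {out}"`.
#' @param premade_msa Optional path to (or alignment tibble of) a
#'   pre-computed alignment; passthrough mode.
#' @return An alignment tibble.
#' @export
align_sequences <- function(records, command = "muscle -in {in} -out {out}",
                            premade_msa = NULL) {
  if (!is.null(premade_msa)) {
    aln <- if (is.data.frame(premade_msa)) {
      new_alignment(premade_msa$id, premade_msa$aligned)
    } else {
      read_msa(premade_msa)
    }
    if (!is.null(records)) check_degap(aln, records)
    return(aln)
  }
  if (is.null(records) || nrow(records) == 0) {
    abort("Cannot align an empty group.")
  }
  exe <- stringr::str_split_1(command, "\\s+")[1]
  if (Sys.which(exe) == "") {
    abort(paste0(
      "Aligner executable '", exe, "' not found on PATH. Either install it, ",
      "change `command`, or supply a pre-computed alignment via `premade_msa`."))
  }
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_group_fasta(records, fin)
  cmd <- stringr::str_replace_all(command,
                                  c("\\{in\\}" = fin, "\\{out\\}" = fout))
  status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = FALSE)
  if (status != 0) {
    abort(paste0("Aligner command failed (exit status ", status, "): ", cmd))
  }
  aln <- read_msa(fout)
  check_degap(aln, records)
  aln
}

check_degap <- function(aln, records) {
  expected <- setNames(records$sequence, records$accession)
  common <- intersect(aln$id, names(expected))
  got <- setNames(degap(aln$aligned), aln$id)[common]
  bad <- common[got != expected[common]]
  if (length(bad) > 0) {
    abort(paste0("De-gapped alignment row(s) do not reproduce the input sequence: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(aln)
}

#' Map an ungapped residue index to its alignment column
#'
#' @param aln An alignment tibble.
#' @param row_id Row identifier.
#' @param residue_index 1-based position in the ungapped sequence.
#' @return 1-based alignment column holding that residue.
#' @export
#' @examples
#' aln <- tibble::tibble(id = "r1", aligned = "M-AR")
#' map_residue_to_column(aln, "r1", 2) # the 'A', column 3
map_residue_to_column <- function(aln, row_id, residue_index) {
  i <- match(row_id, aln$id)
  if (is.na(i)) abort(paste0("No alignment row with id '", row_id, "'."))
  chars <- stringr::str_split_1(aln$aligned[i], "")
  nongap <- which(chars != GAP)
  if (residue_index < 1 || residue_index > length(nongap)) {
    abort(paste0("residue_index ", residue_index, " out of range for row '",
                 row_id, "' (ungapped length ", length(nongap), ")."))
  }
  nongap[residue_index]
}

#' Truncate an alignment, keeping a column suffix
#'
#' Keeps columns `first_kept_col`..n for every row (used for trimming the
#' eutherian P2 alignment down to the post-translationally processed
#' region). Rows that become all-gap are retained and flagged in the
#' `all_gap` attribute.
#'
#' @param aln An alignment tibble.
#' @param first_kept_col 1-based first retained column (inclusive).
#' @return The truncated alignment tibble; attribute `all_gap` lists ids of
#'   rows left with no residues.
#' @export
truncate_alignment <- function(aln, first_kept_col) {
  nc <- n_cols(aln)
  if (first_kept_col < 1 || first_kept_col > nc) {
    abort(paste0("first_kept_col ", first_kept_col,
                 " out of range 1..", nc, "."))
  }
  out <- tibble(id = aln$id,
                aligned = substr(aln$aligned, first_kept_col, nc))
  empty <- out$id[!nzchar(degap(out$aligned))]
  attr(out, "all_gap") <- empty
  attr(out, "first_kept_col") <- first_kept_col
  out
}

#' Locate the P2 processing-site truncation column
#'
#' The processed-P2 truncation site is anchored on a reference row (mouse
#' PRM2 by convention): the alignment column holding the reference
#' sequence's first processed residue. Computing the column from the
#' anchor, rather than hard-coding it, keeps the pipeline valid across
#' aligner outputs.
#'
#' @param aln An alignment tibble.
#' @param reference_id Row id of the reference sequence.
#' @param residue_index 1-based ungapped residue index of the processing
#'   site in the reference (44 for mouse PRM2).
#' @return The 1-based truncation column.
#' @export
p2_truncation_column <- function(aln, reference_id, residue_index = 44) {
  map_residue_to_column(aln, reference_id, residue_index)
}
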