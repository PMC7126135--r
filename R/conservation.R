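#' Mask the leading methionine of every row
#'
#' Initiator methionines are ignored in conservation statistics: for each
#' row whose first non-gap symbol is `M`, that position is flagged and
#' treated as a gap in all downstream column statistics (it counts toward
#' the gap side of the non-gap fraction).
#'
#' @param aln An alignment tibble (`id`, `aligned`).
#' @return The alignment tibble with an added integer column `met_col`: the
#'   masked column for each row, or `NA` when nothing was masked.
#' @export
mask_leading_met <- function(aln) {
  first_nongap <- stringr::str_locate(aln$aligned, "[^-]")[, "start"]
  ch <- substr(aln$aligned, first_nongap, first_nongap)
  met_col <- ifelse(!is.na(first_nongap) & ch == "M", first_nongap, NA_integer_)
  out <- aln
  out$met_col <- as.integer(met_col)
  out
}

# Character matrix view of an alignment with leading-Met masking applied
# (masked cells become gaps). Rows = sequences, columns = alignment columns.
alignment_matrix <- function(aln, mask = TRUE) {
  if (mask && !"met_col" %in% names(aln)) aln <- mask_leading_met(aln)
  m <- matrix(unlist(strsplit(aln$aligned, "", fixed = TRUE)),
              nrow = nrow(aln), byrow = TRUE)
  if (mask) {
    idx <- which(!is.na(aln$met_col))
    if (length(idx) > 0) m[cbind(idx, aln$met_col[idx])] <- GAP
  }
  rownames(m) <- aln$id
  m
}

#' Symbol profile of one alignment column
#'
#' Counts non-gap, non-masked symbols in a column and derives the residue
#' frequencies P(a) over non-gap symbols only, plus the non-gap fraction
#' used for gap weighting. An all-gap column yields an empty profile with
#' `nongap_fraction` 0.
#'
#' @param aln An alignment tibble; leading-Met masking is applied unless a
#'   `met_col` column is already present.
#' @param col 1-based column index.
#' @return A list with `counts` (named integer), `p` (named numeric,
#'   summing to 1 when non-empty), `n_rows`, `n_gap`, `nongap_fraction`.
#' @export
column_profile <- function(aln, col) {
  nc <- n_cols(aln)
  if (col < 1 || col > nc) abort(paste0("Column ", col, " out of range 1..", nc, "."))
  m <- alignment_matrix(aln)
  profile_from_chars(m[, col])
}

profile_from_chars <- function(chars) {
  n_rows <- length(chars)
  residues <- chars[chars != GAP]
  counts <- table(factor(residues, levels = AA_EXTENDED))
  counts <- counts[counts > 0]
  n_res <- length(residues)
  list(
    counts = setNames(as.integer(counts), names(counts)),
    p = if (n_res > 0) as.numeric(counts) / n_res else numeric(),
    n_rows = n_rows,
    n_gap = n_rows - n_res,
    nongap_fraction = n_res / n_rows
  ) -> prof
  if (length(prof$p) > 0) names(prof$p) <- names(counts)
  prof
}

#' Relative entropy of a column profile against a background
#'
#' Kullback-Leibler divergence in bits: sum over residues with P(a) > 0 of
#' P(a) log2(P(a)/Q(a)). Absent symbols contribute 0 (the 0 log 0
#' convention); background frequencies are strictly positive by
#' construction. The score is non-negative whenever P and Q are normalised
#' over the same support; X (with Q(X) = 1) can only contribute a
#' non-positive term.
#'
#' @param profile A column profile from [column_profile()].
#' @param bg A background frequency tibble (see [read_background()]).
#' @return Score in bits.
#' @export
relative_entropy <- function(profile, bg) {
  p <- profile$p
  if (length(p) == 0) abort("Cannot score an all-gap column profile.")
  q <- bg_vector(bg)
  unknown <- setdiff(names(p), names(q))
  if (length(unknown) > 0) {
    abort(paste0("Symbol(s) missing from background: ",
                 paste(unknown, collapse = ", ")))
  }
  sum(p * log2(p / q[names(p)]))
}

#' Gap-weighted conservation score of a column profile
#'
#' The relative entropy multiplied by the column's non-gap fraction, so
#' sparsely populated columns are penalised. An all-gap column scores 0.
#'
#' @inheritParams relative_entropy
#' @return Score in bits.
#' @export
gap_weighted_score <- function(profile, bg) {
  if (profile$nongap_fraction == 0) return(0)
  profile$nongap_fraction * relative_entropy(profile, bg)
}

#' Scan every alignment column for conservation
#'
#' Computes, for each column, the relative entropy against the background,
#' the non-gap fraction, the gap-weighted score, the majority (modal)
#' non-gap symbol with its purity, and the conservation call. A position is
#' conserved only when its gap-weighted score STRICTLY exceeds the
#' threshold — a gapless all-arginine column ties the default all-arginine
#' threshold exactly and is therefore not called.
#'
#' @param aln An alignment tibble; leading-Met masking is applied
#'   internally unless `mask = FALSE`.
#' @param bg A background frequency tibble (default the bundled
#'   UniProt-style abundances).
#' @param threshold Conservation threshold in bits; defaults to
#'   [conservation_threshold()] of `bg` for arginine.
#' @param mask Apply leading-methionine masking (default TRUE).
#' @return A `conservation_scan` tibble with one row per column: `column`,
#'   `d_kl`, `gap_weight`, `g_w`, `conserved`, `majority_symbol`, `purity`.
#'   Attributes: `threshold`, `background_label`, `n_rows`. All-gap columns
#'   get `d_kl` NA and `g_w` 0.
#' @export
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), aligned = c("RRC", "RKC"))
#' scan_alignment(aln)
scan_alignment <- function(aln, bg = uniprot_background(), threshold = NULL,
                           mask = TRUE) {
  if (nrow(aln) == 0) abort("Cannot scan an empty alignment.")
  threshold <- threshold %||% conservation_threshold(bg)
  m <- alignment_matrix(aln, mask = mask)
  q <- bg_vector(bg)
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    prof <- profile_from_chars(m[, j])
    if (length(prof$p) == 0) {
      return(tibble(d_kl = NA_real_, gap_weight = 0, g_w = 0,
                    majority_symbol = NA_character_, purity = NA_real_))
    }
    d <- sum(prof$p * log2(prof$p / q[names(prof$p)]))
    top <- max(prof$counts)
    # deterministic tie-break: alphabetically first modal symbol
    maj <- sort(names(prof$counts)[prof$counts == top])[1]
    tibble(d_kl = d, gap_weight = prof$nongap_fraction,
           g_w = prof$nongap_fraction * d,
           majority_symbol = maj, purity = top / sum(prof$counts))
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out, column = dplyr::row_number(),
                       conserved = .data$g_w > threshold, .before = 1) |>
    dplyr::relocate("column", "d_kl", "gap_weight", "g_w", "conserved",
                    "majority_symbol", "purity")
  attr(out, "threshold") <- threshold
  attr(out, "background_label") <- attr(bg, "source_label") %||% "unlabelled"
  attr(out, "n_rows") <- nrow(aln)
  class(out) <- c("conservation_scan", class(out))
  out
}

#' Conserved positions, most conserved first
#'
#' @param scan A [scan_alignment()] result.
#' @return The conserved rows of the scan, sorted by descending
#'   gap-weighted score.
#' @export
conserved_positions <- function(scan) {
  out <- dplyr::arrange(dplyr::filter(scan, .data$conserved),
                        dplyr::desc(.data$g_w))
  class(out) <- setdiff(class(out), "conservation_scan")
  out
}
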