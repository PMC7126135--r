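#' Read a background amino-acid frequency table
#'
#' Reads a two-column text table (`symbol`, `frequency`) of background
#' amino-acid frequencies Q(a) and augments it with the ambiguity codes used
#' in UniProt sequences: Q(B) = Q(D) + Q(N), Q(Z) = Q(E) + Q(Q), and
#' Q(X) = 1. Setting Q(X) to its upper bound means any X observed in a
#' column contributes a non-positive term to the relative entropy, i.e.
#' unknown residues can only deflate a conservation score, never inflate it.
#'
#' @param path Path to a tab-separated table with columns `symbol` and
#'   `frequency`. Lines starting with `#` are ignored. All 20 standard
#'   amino acids must be present with strictly positive frequencies summing
#'   to approximately 1 (within \[0.98, 1.02\]).
#' @param source_label Label recorded with the frequencies (e.g. a database
#'   release tag). Defaults to the file name.
#'
#' @return A tibble with columns `symbol` and `frequency` covering the 20
#'   standard amino acids plus B, Z and X, carrying attributes
#'   `source_label`.
#' @export
#' @examples
#' bg <- uniprot_background()
#' bg[bg$symbol == "R", ]
read_background <- function(path, source_label = basename(path)) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           symbol = readr::col_character(),
                           frequency = readr::col_double()
                         ))
  missing <- setdiff(AA_STANDARD, tab$symbol)
  if (length(missing) > 0) {
    abort(paste0("Background table is missing residue(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- tab[tab$symbol %in% AA_STANDARD, ]
  if (anyDuplicated(tab$symbol)) {
    abort("Background table lists a residue more than once.")
  }
  if (any(tab$frequency <= 0)) {
    abort("Background frequencies must be strictly positive.")
  }
  total <- sum(tab$frequency)
  if (total < 0.98 || total > 1.02) {
    abort(sprintf(
      "Background frequencies over the 20 standard residues sum to %.4f; expected ~1.",
      total))
  }
  q <- setNames(tab$frequency, tab$symbol)
  aug <- tibble(
    symbol = c(AA_STANDARD, "B", "Z", "X"),
    frequency = c(unname(q[AA_STANDARD]),
                  q[["D"]] + q[["N"]],
                  q[["E"]] + q[["Q"]],
                  1)
  )
  attr(aug, "source_label") <- source_label
  aug
}

#' Bundled UniProt-style background frequencies
#'
#' Returns the background table shipped with the package: a reconstruction
#' of UniProtKB natural-abundance amino-acid statistics with the arginine
#' frequency pinned at 0.0569, the value consistent with an all-arginine
#' conservation threshold of 4.1354 bits under base-2 logarithms.
#'
#' @return A background frequency tibble (see [read_background()]).
#' @export
uniprot_background <- function() {
  path <- system.file("extdata", "uniprotkb_2019_aa_frequencies_synthetic.tsv",
                      package = "protascan", mustWork = TRUE)
  read_background(path, source_label = "UniProtKB 2019 (reconstructed)")
}

#' Uniform background frequencies
#'
#' A null background assigning 1/20 to every standard residue; useful for
#' checking score conventions (an all-`a` column scores log2(20) bits for
#' any residue `a`).
#'
#' @return A background frequency tibble (see [read_background()]).
#' @export
uniform_background <- function() {
  tab <- tibble(
    symbol = c(AA_STANDARD, "B", "Z", "X"),
    frequency = c(rep(1 / 20, 20), 2 / 20, 2 / 20, 1)
  )
  attr(tab, "source_label") <- "uniform"
  tab
}

bg_vector <- function(bg) {
  stopifnot(is.data.frame(bg), all(c("symbol", "frequency") %in% names(bg)))
  setNames(bg$frequency, bg$symbol)
}

#' All-arginine conservation threshold
#'
#' The conservation-call threshold is the score of a hypothetical gapless
#' column composed entirely of one reference residue (arginine by default):
#' log2(1 / Q(reference)). Under the bundled background with Q(R) = 0.0569
#' this is approximately 4.1354 bits. Positions are called conserved only
#' when their gap-weighted score strictly exceeds this value, so an actual
#' all-arginine gapless column ties the threshold and is not called.
#'
#' @param bg A background frequency tibble (see [read_background()]).
#' @param reference_residue Single residue defining the threshold
#'   (default `"R"`).
#'
#' @return Threshold in bits (a single number).
#' @export
#' @examples
#' conservation_threshold(uniprot_background()) # ~4.1354
conservation_threshold <- function(bg, reference_residue = "R") {
  q <- bg_vector(bg)
  if (!reference_residue %in% names(q)) {
    abort(paste0("Residue '", reference_residue, "' not present in background."))
  }
  log2(1 / q[[reference_residue]])
}
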