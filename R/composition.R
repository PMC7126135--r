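#' Charged-residue frequency of one sequence
#'
#' Fraction of residues belonging to a residue set — by default arginine
#' and lysine, the protamine charge carriers (histidine is excluded because
#' it is mostly deprotonated at physiological pH). A leading methionine is
#' excluded from both numerator and denominator, consistent with the
#' initiator-Met masking used in conservation scoring. Matching is
#' case-insensitive.
#'
#' @param sequence Amino-acid string (no gaps).
#' @param residues Character vector of residues to count (default
#'   `c("R", "K")`).
#' @param drop_leading_met Exclude an initial `M` (default TRUE).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' residue_frequency("MRRKA") # 3/4
residue_frequency <- function(sequence, residues = c("R", "K"),
                              drop_leading_met = TRUE) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  if (length(residues) == 0) abort("`residues` must be non-empty.")
  s <- toupper(sequence)
  if (drop_leading_met && startsWith(s, "M")) s <- substr(s, 2, nchar(s))
  if (!nzchar(s)) abort("Sequence is empty after dropping the leading methionine.")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(chars %in% toupper(residues))
}

#' Charged-residue frequencies within an alignment region
#'
#' For each row, the residue-set frequency over the row's NON-GAP symbols
#' inside columns `start_col..end_col` (used for the hypothesised DNA
#' binding regions, e.g. eutherian P1 columns 17-46, metatherian columns
#' 16-56). Dividing by the non-gap count rather than the region width
#' keeps values comparable across rows with different gap patterns. A row
#' with no residues in the region gets `NA`.
#'
#' @param aln An alignment tibble.
#' @param start_col,end_col 1-based inclusive column range.
#' @param residues Residue set (default `c("R", "K")`).
#' @return A tibble with columns `id`, `n_region` (non-gap symbols in the
#'   region) and `frequency`.
#' @export
region_residue_frequency <- function(aln, start_col, end_col,
                                     residues = c("R", "K")) {
  nc <- n_cols(aln)
  if (start_col < 1 || end_col > nc || start_col > end_col) {
    abort(paste0("Region ", start_col, "..", end_col,
                 " invalid for an alignment with ", nc, " columns."))
  }
  if (length(residues) == 0) abort("`residues` must be non-empty.")
  sub <- toupper(substr(aln$aligned, start_col, end_col))
  purrr::map2_dfr(aln$id, sub, function(id, s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars <- chars[chars != GAP]
    tibble(id = id, n_region = length(chars),
           frequency = if (length(chars) == 0) NA_real_
                       else mean(chars %in% toupper(residues)))
  })
}

#' Five-number quartile summary
#'
#' Min, lower quartile, median, upper quartile and max with linear
#' interpolation between closest ranks (`stats::quantile()` type 7, the
#' convention of mainstream numerics). `NA` values are dropped.
#'
#' @param freqs Numeric vector with at least one non-missing value.
#' @return A one-row tibble: `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
quartile_summary <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) == 0) abort("Need at least one non-missing value.")
  q <- quantile(freqs, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                names = FALSE)
  tibble(n = length(freqs), min = q[1], q1 = q[2], median = q[3],
         q3 = q[4], max = q[5])
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption, with
#' Welch-Satterthwaite degrees of freedom; the convention for two
#' degenerate samples with zero variance and equal means is t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(10, 20, 30, 40))
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Welch's t-test needs at least 2 values per sample.")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t_statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 1, mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b)))
    }
    abort("Both samples have zero variance but different means; t is undefined.")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

#' Per-sequence charged-residue frequencies for labelled groups
#'
#' Computes [residue_frequency()] for every sequence in a long tibble of
#' `(group, id, sequence)` rows — the whole-sequence density analysis.
#'
#' @param sequences A tibble with columns `group`, `id`, `sequence`.
#' @param residues Residue set (default `c("R", "K")`).
#' @param drop_leading_met Passed to [residue_frequency()].
#' @return The input tibble with an added `frequency` column.
#' @export
group_composition <- function(sequences, residues = c("R", "K"),
                              drop_leading_met = TRUE) {
  stopifnot(all(c("group", "id", "sequence") %in% names(sequences)))
  dplyr::mutate(
    as_tibble(sequences[c("group", "id", "sequence")]),
    frequency = purrr::map_dbl(.data$sequence, residue_frequency,
                               residues = residues,
                               drop_leading_met = drop_leading_met)
  )
}

#' Quartile summaries per group
#'
#' @param composition Output of [group_composition()] or any tibble with
#'   `group` and `frequency` columns.
#' @return One [quartile_summary()] row per group.
#' @export
composition_summary <- function(composition) {
  composition |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(quartile_summary(.data$frequency), .groups = "drop")
}

#' All pairwise Welch's t-tests between groups
#'
#' @param composition A tibble with `group` and `frequency` columns.
#' @return A tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, and the [welch_t_test()] columns.
#' @export
pairwise_welch <- function(composition) {
  groups <- unique(composition$group)
  if (length(groups) < 2) abort("Need at least two groups to compare.")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- composition$frequency[composition$group == pr[1]]
    b <- composition$frequency[composition$group == pr[2]]
    dplyr::bind_cols(tibble(group_a = pr[1], group_b = pr[2]),
                     welch_t_test(a, b))
  })
}
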