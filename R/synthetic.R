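#' Fish-protamine-like residue composition
#'
#' The default emission composition for synthetic families: arginine-rich
#' (70% R), mimicking fish protamines — the hardest background for an
#' all-arginine conservation threshold, since pure-arginine background
#' columns tie the threshold but must never exceed it. Cysteine, tyrosine
#' and histidine are absent so they are free for planting conserved
#' columns, and methionine is absent so initiator-Met handling stays
#' unambiguous.
#'
#' @return A named probability vector over residues, summing to 1.
#' @export
protamine_composition <- function() {
  c(R = 0.70, K = 0.05, S = 0.07, G = 0.05, A = 0.04,
    P = 0.04, V = 0.03, T = 0.02)
}

normalize_composition <- function(p) {
  if (is.null(names(p)) || any(!names(p) %in% AA_STANDARD)) {
    abort("Composition must be a named vector over standard residues.")
  }
  if (any(p < 0) || sum(p) <= 0) abort("Composition must be non-negative, not all zero.")
  p / sum(p)
}

#' Generate a synthetic protamine-like family with planted columns
#'
#' Simulates a gapped alignment of short arginine-rich sequences with
#' known per-column ground truth. Each cell of a planted column emits the
#' planted residue with probability `purity` and a background draw
#' otherwise; all other cells draw from the background composition. Gaps
#' are inserted i.i.d. per cell at rate `gap_rate` (the conservation score
#' depends only on per-column gap fractions, so block-indel structure is
#' not modelled). With `leading_met = TRUE`, a gapless all-methionine
#' column is prepended, emulating the initiator methionine; planted column
#' indices then shift by one in alignment coordinates, as recorded in the
#' truth table.
#'
#' @param n_sequences Number of sequences (>= 2).
#' @param length Number of core columns (protamine-like: ~30-60).
#' @param background Named emission probabilities (default
#'   [protamine_composition()]); normalised internally.
#' @param planted Optional tibble/data frame with columns `column` (1-based
#'   core column), `residue`, `purity` in (0, 1]. Purity must exceed the
#'   background probability of the planted residue.
#' @param gap_rate Per-cell gap probability in \[0, 1).
#' @param leading_met Prepend an initiator-methionine column (default TRUE).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `records` (record tibble of the de-gapped
#'   sequences), `alignment` (alignment tibble) and `truth` (per-column
#'   tibble: `column`, `label` in {leading_met, planted, background},
#'   `residue`, `purity_target`, `purity_realized`, `gap_fraction`,
#'   `expected_score`).
#' @export
simulate_family <- function(n_sequences = 50, length = 60,
                            background = protamine_composition(),
                            planted = NULL, gap_rate = 0,
                            leading_met = TRUE, seed = 1) {
  problems <- character()
  if (n_sequences < 2) problems <- c(problems, "n_sequences must be >= 2")
  if (length < 1) problems <- c(problems, "length must be >= 1")
  if (gap_rate < 0 || gap_rate >= 1) problems <- c(problems, "gap_rate must be in [0, 1)")
  bgp <- normalize_composition(background)
  if (is.null(planted)) {
    planted <- tibble(column = integer(), residue = character(), purity = numeric())
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0) {
    if (any(planted$column < 1 | planted$column > length))
      problems <- c(problems, "planted columns must lie within 1..length")
    if (any(planted$purity <= 0 | planted$purity > 1))
      problems <- c(problems, "planted purity must be in (0, 1]")
    bg_of <- ifelse(planted$residue %in% names(bgp), bgp[planted$residue], 0)
    if (any(planted$purity <= bg_of))
      problems <- c(problems, "planted purity must exceed the background probability of the residue")
    if (anyDuplicated(planted$column))
      problems <- c(problems, "planted columns must be distinct")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid family configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }

  withr::with_seed(seed, {
    m <- matrix(sample(names(bgp), n_sequences * length, replace = TRUE,
                       prob = bgp),
                nrow = n_sequences)
    for (k in seq_len(nrow(planted))) {
      hit <- stats::runif(n_sequences) < planted$purity[k]
      m[hit, planted$column[k]] <- planted$residue[k]
    }
    if (gap_rate > 0) {
      m[matrix(stats::runif(n_sequences * length) < gap_rate,
               nrow = n_sequences)] <- GAP
    }
    if (leading_met) m <- cbind(rep("M", n_sequences), m)
  })

  rows <- apply(m, 1, paste0, collapse = "")
  ids <- sprintf("SYN%03d", seq_len(n_sequences))
  aln <- tibble(id = ids, aligned = rows)
  seqs <- degap(rows)
  if (any(!nzchar(seqs))) {
    abort("A simulated row contained only gaps; lower gap_rate or set leading_met = TRUE.")
  }
  records <- tibble(
    accession = ids, entry_name = ids, reviewed = FALSE,
    gene_names = rep(list("PRM1"), n_sequences),
    organism = paste("Synthetic organism", seq_len(n_sequences)),
    lineage = rep(list(c("Synthetica", "Protaminae")), n_sequences),
    description = "Synthetic protamine-like protein",
    sequence = seqs
  )

  offset <- as.integer(leading_met)
  all_cols <- seq_len(length + offset)
  label <- rep("background", length(all_cols))
  residue <- rep(NA_character_, length(all_cols))
  target <- rep(NA_real_, length(all_cols))
  if (leading_met) {
    label[1] <- "leading_met"
    residue[1] <- "M"
  }
  if (nrow(planted) > 0) {
    label[planted$column + offset] <- "planted"
    residue[planted$column + offset] <- planted$residue
    target[planted$column + offset] <- planted$purity
  }
  gap_frac <- colMeans(m == GAP)
  pur_real <- purrr::map_dbl(all_cols, function(j) {
    if (is.na(residue[j])) return(NA_real_)
    col <- m[, j]
    col <- col[col != GAP]
    if (length(col) == 0) NA_real_ else mean(col == residue[j])
  })
  truth <- tibble(column = all_cols, label = label, residue = residue,
                  purity_target = target, purity_realized = pur_real,
                  gap_fraction = gap_frac)
  list(records = records, alignment = aln, truth = truth)
}

#' Closed-form expected conservation score of a planted column
#'
#' Expected gap-weighted score of a column emitting residue `residue` with
#' probability `purity` and a background-composition draw otherwise, with
#' gaps at rate `gap_rate`:
#' (1 - gap_rate) * sum_a p(a) log2(p(a)/Q(a)), where p is the mixture
#' purity * delta_residue + (1 - purity) * background. Used to predict
#' which planted columns clear the conservation threshold.
#'
#' @param purity Emission probability of the planted residue, in (0, 1].
#' @param residue Planted residue.
#' @param gap_rate Per-cell gap probability.
#' @param background Named emission composition (default
#'   [protamine_composition()]).
#' @param bg Background frequency tibble for Q (default
#'   [uniprot_background()]).
#' @return Expected score in bits.
#' @export
expected_column_score <- function(purity, residue, gap_rate = 0,
                                  background = protamine_composition(),
                                  bg = uniprot_background()) {
  bgp <- normalize_composition(background)
  p <- (1 - purity) * bgp
  p[residue] <- (p[residue] %|0|% 0) + purity
  p <- p[p > 0]
  q <- bg_vector(bg)
  (1 - gap_rate) * sum(p * log2(p / q[names(p)]))
}

`%|0|%` <- function(x, default) {
  if (length(x) == 0 || is.na(x)) default else x
}

#' Generate two synthetic groups with target charged-residue densities
#'
#' Simulates two groups of ungapped sequences whose per-position residue is
#' arginine or lysine with the group's target probability (R:K at 4:1,
#' reflecting the arginine bias of protamines) and a neutral residue
#' otherwise. Per-sequence R+K frequencies then concentrate binomially
#' around the targets — the generator behind power and calibration checks
#' of the group-composition comparison.
#'
#' @param n_a,n_b Group sizes (>= 2).
#' @param rk_a,rk_b Target R+K probabilities in (0, 1).
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return A tibble with columns `group` ("a"/"b"), `id`, `sequence`.
#' @export
simulate_two_groups <- function(n_a = 50, n_b = 50, rk_a = 0.6, rk_b = 0.7,
                                length = 50, seed = 1) {
  stopifnot(n_a >= 2, n_b >= 2, length >= 1,
            rk_a > 0, rk_a < 1, rk_b > 0, rk_b < 1)
  other <- c(A = 0.20, G = 0.15, S = 0.20, T = 0.15, P = 0.10,
             V = 0.10, Y = 0.10)
  gen <- function(n, rk, prefix) {
    seqs <- purrr::map_chr(seq_len(n), function(i) {
      charged <- stats::runif(length) < rk
      chars <- ifelse(charged,
                      sample(c("R", "K"), length, replace = TRUE,
                             prob = c(0.8, 0.2)),
                      sample(names(other), length, replace = TRUE,
                             prob = other))
      paste0(chars, collapse = "")
    })
    tibble(group = prefix, id = sprintf("%s%03d", toupper(prefix), seq_len(n)),
           sequence = seqs)
  }
  withr::with_seed(seed, dplyr::bind_rows(gen(n_a, rk_a, "a"),
                                          gen(n_b, rk_b, "b")))
}
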