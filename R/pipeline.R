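#' Run the full protamine conservation pipeline
#'
#' Orchestrates, for each configured group: record ingestion, rule
#' filtering, per-organism deduplication, listed-member removal, alignment
#' (external aligner or pre-computed passthrough), optional truncation at
#' an anchored processing site, leading-Met masking, the conservation scan
#' and the charged-residue density analysis, finishing with pairwise
#' Welch's t-tests between group density distributions. Given identical
#' inputs and configuration the result is deterministic.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{records}{A record tibble, or a path to a UniProt-style FASTA
#'       (`.fasta`/`.fa`) or tab-separated export (`.tsv`/`.tab`).}
#'     \item{groups}{Named list; each entry a list with `rule` (a
#'       [group_rule()]) and optionally `premade_msa` (path or alignment
#'       tibble), `aligner_command` (template for [align_sequences()]),
#'       `exclusions` + `exclusion_reason`, `truncate_anchor` (list with
#'       `reference_id`, `residue_index`) and `region` (`c(start, end)`
#'       columns of the hypothesised DNA-binding region). Exactly one of
#'       `premade_msa`/`aligner_command` must be usable per group.}
#'     \item{background}{Background tibble or path (default bundled
#'       UniProt-style table).}
#'     \item{residues}{Charged residue set (default `c("R", "K")`).}
#'     \item{out_dir}{Optional directory; per-group conservation TSVs and
#'       the composition/test tables are written there.}
#'   }
#' @return A `report_bundle`: list with `groups` (per group: `members`,
#'   `alignment`, `scan`, `conserved`), `composition` (whole-sequence
#'   densities; truncated groups use their processed sequences), `summary`
#'   (per-group quartiles), `density` (the per-group distribution entering
#'   the tests: region frequencies where a region is configured, else
#'   whole-sequence), `tests` (pairwise Welch results), `provenance`, and
#'   `config_hash`. Every table carries `config_hash` and
#'   `background_label` attributes.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$groups) || length(config$groups) == 0) {
    abort("Pipeline configuration defines no groups; nothing to report.")
  }
  records <- load_records(config$records)
  bg <- config$background %||% uniprot_background()
  if (is.character(bg)) bg <- read_background(bg)
  residues <- config$residues %||% c("R", "K")
  cfg_hash <- rlang::hash(config)
  bg_label <- attr(bg, "source_label") %||% "unlabelled"

  group_results <- purrr::imap(config$groups, function(gc, gname) {
    run_group_stage(gname, gc, records, bg)
  })

  composition <- purrr::imap_dfr(group_results, function(gr, gname) {
    group_composition(
      tibble(group = gname, id = gr$processed$id, sequence = gr$processed$sequence),
      residues = residues)
  })
  density <- purrr::imap_dfr(group_results, function(gr, gname) {
    gc <- config$groups[[gname]]
    if (!is.null(gc$region)) {
      rf <- region_residue_frequency(gr$alignment, gc$region[1], gc$region[2],
                                     residues = residues)
      tibble(group = gname, id = rf$id, frequency = rf$frequency,
             basis = "region")
    } else {
      cw <- composition[composition$group == gname, ]
      tibble(group = gname, id = cw$id, frequency = cw$frequency,
             basis = "whole_sequence")
    }
  })
  tests <- if (length(group_results) >= 2) pairwise_welch(density) else NULL
  provenance <- purrr::imap_dfr(group_results, function(gr, gname) {
    dplyr::mutate(gr$provenance, group = gname, .before = 1)
  })

  bundle <- list(
    groups = purrr::map(group_results,
                        ~ .x[c("members", "alignment", "scan", "conserved")]),
    composition = composition,
    summary = composition_summary(composition),
    density = density,
    tests = tests,
    provenance = provenance,
    config_hash = cfg_hash,
    background_label = bg_label
  )
  bundle <- stamp_tables(bundle, cfg_hash, bg_label)
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

load_records <- function(records) {
  if (is.null(records)) return(NULL)
  if (is.data.frame(records)) return(validate_records(as_tibble(records)))
  if (is.character(records) && length(records) == 1) {
    if (grepl("\\.(tsv|tab|txt)$", records, ignore.case = TRUE)) {
      return(read_uniprot_tab(records))
    }
    return(read_uniprot_fasta(records))
  }
  abort("`records` must be a record tibble or a single file path.")
}

run_group_stage <- function(gname, gc, records, bg) {
  step <- function(what) paste0("[group ", gname, "] ", what)
  members <- NULL
  if (!is.null(records) && !is.null(gc$rule)) {
    members <- tryCatch(filter_group(records, gc$rule),
                        error = function(e) abort(step(conditionMessage(e))))
    if (isTRUE(gc$rule$dedupe_per_organism)) {
      members <- dedupe_per_organism(members)
    }
    if (!is.null(gc$exclusions)) {
      members <- remove_members(members, gc$exclusions,
                                gc$exclusion_reason %||% "configured exclusion")
    }
  }
  if (is.null(gc$premade_msa) && is.null(gc$aligner_command) ) {
    abort(step("needs either `premade_msa` or `aligner_command`."))
  }
  aln <- tryCatch(
    align_sequences(members,
                    command = gc$aligner_command %||% "muscle -in {in} -out {out}",
                    premade_msa = gc$premade_msa),
    error = function(e) abort(step(conditionMessage(e))))
  prov <- attr(members, "provenance") %||%
    tibble(step = character(), n_in = integer(), n_out = integer(),
           note = character())
  if (!is.null(gc$truncate_anchor)) {
    cut <- p2_truncation_column(aln, gc$truncate_anchor$reference_id,
                                gc$truncate_anchor$residue_index %||% 44)
    aln <- truncate_alignment(aln, cut)
    prov <- add_provenance(prov, "truncate_alignment",
                           n_in = nrow(aln), n_out = nrow(aln),
                           note = paste0("first kept column ", cut))
  }
  scan <- scan_alignment(aln, bg = bg)
  processed <- tibble(id = aln$id, sequence = degap(aln$aligned))
  processed <- processed[nzchar(processed$sequence), ]
  list(members = members, alignment = aln, scan = scan,
       conserved = conserved_positions(scan),
       processed = processed, provenance = prov)
}

stamp_tables <- function(bundle, cfg_hash, bg_label) {
  stamp <- function(x) {
    if (is.data.frame(x)) {
      attr(x, "config_hash") <- cfg_hash
      attr(x, "background_label") <- bg_label
    }
    x
  }
  for (nm in c("composition", "summary", "density", "tests", "provenance")) {
    bundle[[nm]] <- stamp(bundle[[nm]])
  }
  bundle$groups <- purrr::map(bundle$groups, ~ purrr::map(.x, stamp))
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (gname in names(bundle$groups)) {
    g <- bundle$groups[[gname]]
    readr::write_tsv(as_tibble(g$scan),
                     file.path(out_dir, paste0(gname, "_conservation.tsv")))
    readr::write_tsv(as_tibble(g$conserved),
                     file.path(out_dir, paste0(gname, "_conserved_positions.tsv")))
    write_msa(g$alignment, file.path(out_dir, paste0(gname, "_alignment.fasta")))
  }
  readr::write_tsv(bundle$composition, file.path(out_dir, "composition.tsv"))
  readr::write_tsv(bundle$summary, file.path(out_dir, "composition_summary.tsv"))
  readr::write_tsv(bundle$density, file.path(out_dir, "density.tsv"))
  if (!is.null(bundle$tests)) {
    readr::write_tsv(bundle$tests, file.path(out_dir, "pairwise_welch.tsv"))
  }
  readr::write_tsv(bundle$provenance, file.path(out_dir, "provenance.tsv"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$groups), " group(s); config ",
      substr(x$config_hash, 1, 8), "; background: ", x$background_label,
      "\n", sep = "")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat("  ", gname, ": ", nrow(g$alignment), " rows x ",
        n_cols(g$alignment), " cols, ", nrow(g$conserved),
        " conserved position(s)\n", sep = "")
  }
  if (!is.null(x$tests)) {
    cat("  pairwise Welch tests:", nrow(x$tests), "comparison(s)\n")
  }
  invisible(x)
}
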