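#' Render an alignment with conserved columns highlighted
#'
#' Text mode prints a column ruler (ticks every 10 columns), the alignment
#' rows, and a marker row with `*` under every conserved column. HTML mode
#' emits a `<table>` whose `<colgroup>` carries exactly one
#' `class="conserved"` `<col>` element per conserved column.
#'
#' @param aln An alignment tibble.
#' @param scan The matching [scan_alignment()] result (same column count).
#' @param format `"text"` or `"html"`.
#' @return A single string (text block or HTML document fragment).
#' @export
render_highlighted_alignment <- function(aln, scan, format = c("text", "html")) {
  format <- match.arg(format)
  nc <- n_cols(aln)
  if (nrow(scan) != nc) {
    abort(paste0("Scan has ", nrow(scan), " columns but alignment has ",
                 nc, "."))
  }
  if (format == "text") {
    render_text(aln, scan, nc)
  } else {
    render_html(aln, scan, nc)
  }
}

render_text <- function(aln, scan, nc) {
  pad <- max(nchar(aln$id), 0) + 2
  lead <- strrep(" ", pad)
  ticks <- paste0(rep_len(c(rep(".", 9), "|"), nc), collapse = "")
  numbers <- character(nc)
  for (t in seq_len(nc %/% 10) * 10) {
    lab <- as.character(t)
    numbers[(t - nchar(lab) + 1):t] <- strsplit(lab, "")[[1]]
  }
  numbers[numbers == ""] <- " "
  marker <- ifelse(scan$conserved, "*", " ")
  lines <- c(
    paste0(lead, paste0(numbers, collapse = "")),
    paste0(lead, ticks),
    paste0(formatC(aln$id, width = -pad), aln$aligned),
    paste0(lead, paste0(marker, collapse = ""))
  )
  paste0(lines, collapse = "\n")
}

render_html <- function(aln, scan, nc) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cols <- ifelse(scan$conserved,
                 "    <col class=\"conserved\"/>",
                 "    <col/>")
  header <- paste0("    <th></th>",
                   paste0("<th>", ifelse(seq_len(nc) %% 10 == 0, seq_len(nc), ""),
                          "</th>", collapse = ""))
  rows <- purrr::map_chr(seq_len(nrow(aln)), function(i) {
    cells <- strsplit(aln$aligned[i], "", fixed = TRUE)[[1]]
    paste0("    <tr><th>", esc(aln$id[i]), "</th>",
           paste0("<td>", esc(cells), "</td>", collapse = ""), "</tr>")
  })
  paste(c("<table class=\"protascan-alignment\">",
          "  <colgroup>",
          "    <col/>",  # id column
          cols,
          "  </colgroup>",
          paste0("  <thead><tr>\n", header, "\n  </tr></thead>"),
          "  <tbody>",
          rows,
          "  </tbody>",
          "</table>"),
        collapse = "\n")
}
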