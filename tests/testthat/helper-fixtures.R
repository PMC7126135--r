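# Fixtures are built in code; nothing binary is stored on disk.

make_record <- function(accession, organism, lineage, genes = character(),
                        reviewed = FALSE, description = "Sperm protamine P1",
                        sequence = "MARYRCCRSQSRSRYYRQ") {
  tibble::tibble(
    accession = accession, entry_name = accession, reviewed = reviewed,
    gene_names = list(genes), organism = organism, lineage = list(lineage),
    description = description, sequence = sequence
  )
}

eutherian_lineage <- c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Eutheria")
metatherian_lineage <- c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Metatheria")
fish_lineage <- c("Eukaryota", "Metazoa", "Chordata", "Actinopterygii")

# A small mixed record set exercising all four group rules.
mixed_records <- function() {
  dplyr::bind_rows(
    make_record("P02320", "Bos taurus", eutherian_lineage, c("PRM1"),
                reviewed = TRUE),
    make_record("Q9MOUS", "Mus musculus", eutherian_lineage, c("Prm1")),
    make_record("Q9PRM2", "Mus musculus", eutherian_lineage, c("Prm2"),
                description = "Sperm protamine P2",
                sequence = "MVRYRVRSLSERSHEVYRQQLHGQEQGHHGQEEQGLSPEHVEVYERTHGQSHYRRRHCSRRRLHRIHRRQHRSCRRRKRRSCRHRRRHRRGCRRSRRRRRCRCRKCRRHHH"),
    make_record("Q8KANG", "Macropus rufus", metatherian_lineage, c("PRM1"),
                sequence = "MARYRHSRSRSRSRYRRRRRARHRRRRRSYGRRRYSRRRVRRRRRRGYSRRRYSVRQRSRQ"),
    make_record("P69014", "Oncorhynchus mykiss", fish_lineage, character(),
                reviewed = TRUE, description = "Protamine",
                sequence = "MPRRRRSSSRPVRRRRRPRVSRRRRRRGGRRRR"),
    make_record("A0FISH", "Danio rerio", fish_lineage, character(),
                description = "Protamine-like protein",
                sequence = "MARRRRSRSRSRS")
  )
}

write_fasta_fixture <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

uniprot_fasta_lines <- c(
  ">sp|P02320|HSP1_BOVIN Sperm protamine P1 OS=Bos taurus OX=9913 GN=PRM1 PE=1 SV=2",
  "MARYRCCRSQSRSRYYRQRQRSRRRRRRSCQTQRRA",
  "MRCCRPRYRPRCRRH",
  ">tr|Q9FAKE|Q9FAKE_PIG Protamine-like protein OS=Sus scrofa OX=9823 GN=PRM9 PE=4 SV=1",
  "MARYRCCRSR"
)

make_alignment <- function(rows, ids = sprintf("r%d", seq_along(rows))) {
  tibble::tibble(id = ids, aligned = rows)
}

# Independent brute-force conservation oracle: loops over rows and columns
# directly on the strings, uses natural logs rescaled to bits, and never
# touches the package's column machinery.
oracle_scan <- function(rows, q, mask = TRUE) {
  chars <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  nc <- length(chars[[1]])
  if (mask) {
    for (i in seq_along(chars)) {
      j <- 1
      while (j <= nc && chars[[i]][j] == "-") j <- j + 1
      if (j <= nc && chars[[i]][j] == "M") chars[[i]][j] <- "-"
    }
  }
  out <- data.frame(column = seq_len(nc), d_kl = NA_real_, g_w = NA_real_)
  for (j in seq_len(nc)) {
    col <- vapply(chars, `[`, character(1), j)
    res <- col[col != "-"]
    if (length(res) == 0) {
      out$g_w[j] <- 0
      next
    }
    d <- 0
    for (a in unique(res)) {
      p <- sum(res == a) / length(res)
      d <- d + p * (log(p) - log(q[[a]])) / log(2)
    }
    out$d_kl[j] <- d
    out$g_w[j] <- d * length(res) / length(col)
  }
  out
}

random_alignment <- function(n_rows, n_cols, gap_prob = 0.15,
                             alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                          "G", "H", "I", "L", "K", "M", "F",
                                          "P", "S", "T", "W", "Y", "V",
                                          "B", "Z", "X")) {
  m <- matrix(sample(alphabet, n_rows * n_cols, replace = TRUE),
              nrow = n_rows)
  m[matrix(stats::runif(n_rows * n_cols) < gap_prob, nrow = n_rows)] <- "-"
  make_alignment(apply(m, 1, paste0, collapse = ""))
}
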