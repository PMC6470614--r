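# Shared fixture builders and the independent brute-force match oracle.

write_peptide_file <- function(rows, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  header <- paste(c("sequence", "ic50_uM"), collapse = sep)
  lines <- c(header, vapply(rows, function(r)
    paste(c(r[[1]], r[[2]]), collapse = sep), character(1)))
  writeLines(lines, path)
  path
}

# Hand-written miniature GenBank record: two forward CDS (one with a
# deposited translation, one conceptual-only), one CDS on the complement
# strand, a spliced (join) CDS, and rRNA/tRNA features.
write_mini_genbank <- function() {
  path <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  #          1-9: ATGGCTTAA (-> MA); 10-18 revcomp(ATGAAATAA)=TTATTTCAT (-> MK)
  # join CDS: 19..24 + 28..33 = ATGTGT + GGTTAA -> MCG
  seq <- paste0("ATGGCTTAA", "TTATTTCAT", "ATGTGT", "CCC", "GGTTAA",
                "ACGTACGTACGT")
  writeLines(c(
    sprintf("LOCUS       MINI %d bp    DNA     linear   SYN", nchar(seq)),
    "DEFINITION  hand-written miniature test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    "     CDS             1..9",
    '                     /gene="genA"',
    '                     /translation="MKL*"',
    "     CDS             complement(10..18)",
    '                     /locus_tag="locB"',
    "     CDS             join(19..24,28..33)",
    '                     /product="hypothetical protein C"',
    "     rRNA            34..39",
    '                     /gene="rrs"',
    "     rRNA            40..45",
    "     tRNA            1..6",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//"), path)
  path
}

# Independent occurrence oracle: perl lookahead regex, a different engine
# and code path from the window scanner it checks.
oracle_positions <- function(peptide, sequence) {
  m <- gregexpr(paste0("(?=", peptide, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

oracle_scan <- function(peptides, proteins, mode = "positions") {
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    for (pep in peptides$sequence) {
      pos <- oracle_positions(pep, proteins$sequence[i])
      if (mode == "unique_pairs" && length(pos)) pos <- pos[1]
      if (length(pos)) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = pep, record_id = proteins$record_id[i], position = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(peptide = character(0), record_id = character(0),
               position = integer(0), stringsAsFactors = FALSE)
  }
  hits[order(hits$record_id, hits$position, hits$peptide), , drop = FALSE]
}

# Expected class-by-group cell counts implied by a generator ledger.
expected_counts_from_ledger <- function(plants, proteins, grouping,
                                        mode = "positions") {
  if (mode == "unique_pairs") {
    plants <- plants[!duplicated(plants[, c("record_id", "peptide")]), ,
                     drop = FALSE]
  }
  groups <- switch(grouping,
    category = tripepscan:::CATEGORIES,
    photosystem_subcategory = tripepscan:::PS_SUBCATEGORIES,
    protein = unique(proteins$gene_symbol))
  g <- switch(grouping,
    category = plants$category,
    photosystem_subcategory = ifelse(plants$category == "Photosystems",
                                     plants$subcategory, NA),
    protein = plants$gene_symbol)
  cls <- terminal_class(plants$peptide)
  keep <- !is.na(g)
  m <- table(factor(cls[keep], levels = tripepscan:::TERMINAL_CLASSES),
             factor(g[keep], levels = groups))
  matrix(as.integer(m), nrow = nrow(m),
         dimnames = list(rownames(m), colnames(m)))
}

random_protein_set <- function(n_prot, len_range, alphabet = c("A", "C", "D", "G")) {
  data.frame(
    record_id = sprintf("R%03d", seq_len(n_prot)),
    gene_symbol = sprintf("g%03d", seq_len(n_prot)),
    sequence = vapply(seq_len(n_prot), function(i) {
      paste(sample(alphabet, sample(len_range, 1), replace = TRUE),
            collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE) -> df
  df$length <- nchar(df$sequence)
  df$flagged <- FALSE
  df
}

random_tripeptides <- function(n, alphabet = c("A", "C", "D", "G")) {
  peps <- unique(vapply(seq_len(3 * n), function(i)
    paste(sample(alphabet, 3, replace = TRUE), collapse = ""), character(1)))
  peps <- peps[seq_len(min(n, length(peps)))]
  data.frame(sequence = peps, ic50_uM = 5, source = NA_character_,
             terminal_class = terminal_class(peps), stringsAsFactors = FALSE)
}
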