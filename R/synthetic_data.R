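# Synthetic proteomes with planted tripeptide occurrences and an exact
# ground-truth ledger, so every pipeline stage is testable without any
# database download.

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a synthetic-proteome generator configuration
#'
#' @param n_proteins named integer vector: proteins per functional category
#'   (names from the 7-category set); unnamed scalar means that many
#'   proteins in every category.
#' @param length_range two integers, uniform protein length range in
#'   residues; minimum 10.
#' @param background_frequencies named numeric over (a subset of) the 20
#'   standard AAs, summing to 1; default uniform over all 20.
#' @param plants list of `list(peptide=, count=, categories=)` entries: each
#'   protein of a listed category receives `count` non-overlapping copies of
#'   the tripeptide at uniformly drawn offsets. `categories = NULL` targets
#'   every category present.
#' @param accidental_free when `TRUE`, background residues are drawn from
#'   the alphabet minus every planted peptide's residues, so the ledger's
#'   planted counts are provably the true occurrence counts.
#' @param seed integer seed driving one explicit pseudo-random stream.
#' @return validated config list of class `generator_config`.
#' @export
generator_config <- function(n_proteins, length_range = c(100L, 300L),
                             background_frequencies = NULL,
                             plants = list(), accidental_free = TRUE,
                             seed = 1L) {
  if (is.null(names(n_proteins))) {
    stopifnot(length(n_proteins) == 1L)
    n_proteins <- stats::setNames(rep(as.integer(n_proteins), length(CATEGORIES)),
                                  CATEGORIES)
  }
  if (!all(names(n_proteins) %in% CATEGORIES)) {
    stop_fmt("unknown category in n_proteins: %s",
             paste(setdiff(names(n_proteins), CATEGORIES), collapse = ", "))
  }
  length_range <- as.integer(length_range)
  stopifnot(length(length_range) == 2L, length_range[1] >= 10L,
            length_range[2] >= length_range[1])
  if (is.null(background_frequencies)) {
    background_frequencies <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (!all(names(background_frequencies) %in% AA_STANDARD) ||
      abs(sum(background_frequencies) - 1) > 1e-8) {
    stop_fmt("background frequencies must be over standard AAs and sum to 1")
  }
  for (p in plants) {
    if (!is_valid_tripeptide(toupper(p$peptide %||% ""))) {
      stop_fmt("planted peptide '%s' is not a valid tripeptide", p$peptide %||% "")
    }
    if (is.null(p$count) || p$count < 1L) stop_fmt("plant count must be >= 1")
  }
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 background_frequencies = background_frequencies,
                 plants = plants, accidental_free = accidental_free,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# k 0-based start offsets for length-3 windows in a protein of len residues,
# uniform over sorted configurations with at least one background residue
# between consecutive plants. The spacer is what makes accidental-free mode
# provably exact: every window not equal to a planted window then contains a
# background residue, and background residues are outside the plant alphabet.
draw_plant_offsets <- function(len, k) {
  slots <- len - 2L - 4L * (k - 1L)
  if (k > 0L && slots < 1L) {
    stop_fmt("cannot place %d spaced tripeptides in %d residues (capacity %d)",
             k, len, (len + 1L) %/% 4L)
  }
  if (k == 0L) return(integer(0))
  base <- sort(sample.int(slots, k))
  base - 1L + 4L * (seq_len(k) - 1L)
}

#' Generate a synthetic proteome with planted tripeptides
#'
#' Protein lengths are uniform over the configured range; residues are drawn
#' i.i.d. from the background frequencies (restricted away from planted
#' residues in accidental-free mode); planted peptides are written over
#' non-overlapping uniformly drawn windows. Gene symbols are taken from the
#' packaged schema so the output classifies without fallback warnings. The
#' run is reproducible: the same config (including seed) gives identical
#' output.
#'
#' @param config a [generator_config()].
#' @return list with `proteins` (classified record data frame), `peptides`
#'   (the planted peptide set with placeholder IC50s), and `ground_truth`:
#'   `plants` (record_id/gene_symbol/category/subcategory/peptide/position),
#'   `totals_by_category`, `totals_by_protein`, `accidental_free`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  plant_peps <- vapply(config$plants, function(p) toupper(p$peptide), character(1))
  bg <- config$background_frequencies
  if (config$accidental_free && length(plant_peps)) {
    banned <- unique(unlist(strsplit(plant_peps, "")))
    bg <- bg[setdiff(names(bg), banned)]
    if (!length(bg) || sum(bg) <= 0) {
      stop_fmt("accidental-free mode leaves no background alphabet")
    }
    bg <- bg / sum(bg)
  }
  schema <- default_schema()
  with_seed(config$seed, {
    rows <- list(); ledger <- list()
    idx <- 0L
    for (cat in names(config$n_proteins)) {
      n <- config$n_proteins[[cat]]
      if (n < 1L) next
      pool <- schema$gene[schema$category == cat]
      # more proteins than curated symbols -> reuse symbols as gene copies,
      # so the category structure survives classification
      symbols <- rep(pool, length.out = n)
      for (j in seq_len(n)) {
        idx <- idx + 1L
        len <- sample_one(seq(config$length_range[1], config$length_range[2]))
        seq_chars <- sample(names(bg), len, replace = TRUE, prob = bg)
        rid <- sprintf("SYN%04d", idx)
        applicable <- Filter(function(p) is.null(p$categories) ||
                               cat %in% p$categories, config$plants)
        counts <- vapply(applicable, function(p) as.integer(p$count), integer(1))
        k <- sum(counts)
        if (k > 0L) {
          offs <- draw_plant_offsets(len, k)
          peps <- rep(vapply(applicable, function(p) toupper(p$peptide),
                             character(1)), counts)
          peps <- sample(peps)        # shuffle which plant lands where
          for (t in seq_len(k)) {
            seq_chars[(offs[t] + 1L):(offs[t] + 3L)] <- residues(peps[t])
          }
          ledger[[length(ledger) + 1L]] <- data.frame(
            record_id = rid, gene_symbol = symbols[j], category = cat,
            peptide = peps, position = offs, stringsAsFactors = FALSE)
        }
        rows[[idx]] <- data.frame(record_id = rid, gene_symbol = symbols[j],
                                  sequence = paste(seq_chars, collapse = ""),
                                  length = len, flagged = FALSE,
                                  stringsAsFactors = FALSE)
      }
    }
    proteins <- classify_proteins(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                                  schema)
    plants <- if (length(ledger)) {
      do.call(rbind, c(ledger, list(make.row.names = FALSE)))
    } else {
      data.frame(record_id = character(0), gene_symbol = character(0),
                 category = character(0), peptide = character(0),
                 position = integer(0), stringsAsFactors = FALSE)
    }
    plants$subcategory <- proteins$subcategory[match(plants$record_id,
                                                     proteins$record_id)]
    peptides <- if (length(plant_peps)) {
      data.frame(sequence = unique(plant_peps), ic50_uM = 5,
                 source = "synthetic plant",
                 terminal_class = terminal_class(unique(plant_peps)),
                 stringsAsFactors = FALSE)
    } else empty_peptide_table()
    totals_cat <- vapply(CATEGORIES, function(cc)
      sum(plants$category == cc), integer(1))
    totals_prot <- if (nrow(plants)) {
      stats::aggregate(peptide ~ record_id, plants, length)
    } else data.frame(record_id = character(0), peptide = integer(0))
    list(proteins = proteins, peptides = peptides,
         ground_truth = list(plants = plants,
                             totals_by_category = totals_cat,
                             totals_by_protein = totals_prot,
                             accidental_free = config$accidental_free))
  })
}

# Fixed reverse-translation codons (all decode to their AA under table 11).
REV_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Write a synthetic GenBank fixture for a protein set
#'
#' Reverse-translates every protein into a single synthetic genome record:
#' one CDS feature per protein with `/gene` and `/translation` qualifiers,
#' separated by short spacers. The file re-reads through
#' [read_genbank_proteins()] with identical sequences and symbols.
#'
#' @param proteins protein record data frame.
#' @param path output path.
#' @param locus LOCUS name for the synthetic record.
#' @return invisibly, the path.
#' @export
write_genbank_fixture <- function(proteins, path, locus = "SYNPLASTID") {
  spacer <- "ACGTACGTAC"
  dna_parts <- character(0); feats <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(proteins))) {
    dna_parts <- c(dna_parts, spacer); pos <- pos + nchar(spacer)
    cds <- paste0(paste(REV_CODON[residues(proteins$sequence[i])], collapse = ""),
                  "TAA")
    feats <- c(feats,
               sprintf("     CDS             %d..%d", pos + 1L, pos + nchar(cds)),
               sprintf('                     /gene="%s"', proteins$gene_symbol[i]),
               wrap_qualifier(sprintf('/translation="%s"', proteins$sequence[i])))
    dna_parts <- c(dna_parts, cds); pos <- pos + nchar(cds)
  }
  dna <- paste0(paste(dna_parts, collapse = ""), spacer)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   SYN", locus, nchar(dna)), con)
  writeLines("DEFINITION  synthetic proteome fixture (tripepscan).", con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(dna)), con)
  writeLines(feats, con)
  writeLines("ORIGIN", con)
  starts <- seq(1L, nchar(dna), by = 60L)
  writeLines(sprintf("%9d %s", starts,
                     tolower(substring(dna, starts, pmin(starts + 59L, nchar(dna))))),
             con)
  writeLines("//", con)
  invisible(path)
}

wrap_qualifier <- function(text, width = 58L) {
  pieces <- substring(text, seq(1L, nchar(text), by = width),
                      pmin(seq(1L, nchar(text), by = width) + width - 1L, nchar(text)))
  paste0("                     ", pieces)
}

#' Write a full synthetic fixture bundle
#'
#' Emits the same formats the pipeline consumes: a protein FASTA plus
#' annotation TSV, a synthetic GenBank record, the peptide table, and the
#' ground-truth ledger as JSON.
#'
#' @param gen output of [generate_proteome()] or [make_paper_like_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of written paths.
#' @export
write_fixture_bundle <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             genbank = file.path(dir, "genome.gb"),
             peptides = file.path(dir, "peptides.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_protein_fasta(gen$proteins, paths["fasta"], paths["annotations"])
  write_genbank_fixture(gen$proteins, paths["genbank"])
  utils::write.table(gen$peptides[, c("sequence", "ic50_uM", "source")],
                     paths["peptides"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(gen$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' A miniature proteome fixture shaped like the study system
#'
#' About 20 proteins across the 7 functional categories (roughly 2,000
#' residues), with a 10-peptide database — the 4 published catch-all-class
#' tripeptides LVQ, LVE, IWH and GPM plus 6 synthetic fillers — planted
#' accidental-free so the ledger is exact. Structure mirrors the study
#' proteome at about one-hundredth scale; all sequence content is synthetic.
#'
#' @param seed integer seed.
#' @return as [generate_proteome()].
#' @export
make_paper_like_fixture <- function(seed = 42L) {
  fillers <- c("IPP", "VPP", "HLP", "MEG", "WIL", "QGV")
  xxx4 <- c("LVQ", "LVE", "IWH", "GPM")
  plants <- c(
    lapply(fillers, function(p) list(peptide = p, count = 1L, categories = NULL)),
    lapply(xxx4, function(p) list(peptide = p, count = 1L,
                                  categories = c("Photosystems", "Metabolism",
                                                 "Unknown")))
  )
  cfg <- generator_config(
    n_proteins = c("Genetic System" = 2L, "Ribosomal Proteins" = 3L,
                   "Photosystems" = 6L, "ATP Synthesis" = 2L,
                   "Metabolism" = 3L, "Transport" = 2L, "Unknown" = 2L),
    length_range = c(80L, 120L),
    plants = plants, accidental_free = TRUE, seed = seed)
  gen <- generate_proteome(cfg)
  gen$peptides <- data.frame(
    sequence = c(fillers, xxx4),
    ic50_uM = c(5, 9, 12, 15, 7, 18, 5, 12, 3.5, 17),
    source = c(rep("synthetic filler", 6), rep("published catch-all class", 4)),
    stringsAsFactors = FALSE)
  gen$peptides$terminal_class <- terminal_class(gen$peptides$sequence)
  gen
}
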