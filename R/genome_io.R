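#' Extract translated protein coding genes from a GenBank record
#'
#' Builds one protein record per CDS feature. The deposited `/translation`
#' qualifier is authoritative when present (with a warning if it disagrees
#' with the conceptual translation); otherwise the CDS is translated under
#' the bacterial/plastid genetic code (NCBI table 11). Trailing stop symbols
#' are removed. The gene symbol is taken from `/gene`, falling back to
#' `/locus_tag`, then `/product`. Internal stops in a conceptual translation
#' flag the record rather than dropping it.
#'
#' @param path GenBank flat file with CDS features.
#' @param dedupe_genes collapse records with identical (gene symbol,
#'   sequence) pairs — gene duplicates inside repeated regions — to a single
#'   record. Default `FALSE`: each annotated copy is kept.
#' @return data frame of protein records: `record_id`, `gene_symbol`,
#'   `sequence`, `length`, `flagged` (internal-stop flag).
#' @export
read_genbank_proteins <- function(path, dedupe_genes = FALSE) {
  gb <- parse_genbank(path)
  cds <- Filter(function(f) f$type == "CDS", gb$features)
  out <- vector("list", length(cds))
  for (i in seq_along(cds)) {
    f <- cds[[i]]
    q <- f$qualifiers
    symbol <- q$gene
    if (is.null(symbol)) symbol <- q$locus_tag
    if (is.null(symbol)) symbol <- q$product
    if (is.null(symbol) || !nzchar(symbol)) {
      stop_fmt("CDS %d (%s): no /gene, /locus_tag or /product qualifier",
               i, f$location_text)
    }
    flagged <- FALSE
    deposited <- q$translation
    if (!is.null(deposited)) {
      aa <- sub("\\*$", "", toupper(gsub("[[:space:]]", "", deposited)))
      if (!is.null(f$location)) {
        conceptual <- tryCatch(translate_cds(feature_dna(gb$sequence, f$location)),
                               error = function(e) NULL)
        if (!is.null(conceptual) && conceptual != aa) {
          warn_fmt("CDS %s: /translation disagrees with conceptual translation; keeping /translation",
                   symbol)
        }
      }
    } else {
      if (is.null(f$location)) {
        stop_fmt("CDS %d (%s): no /translation and unparsable coordinates '%s'",
                 i, symbol, f$location_text)
      }
      aa <- translate_cds(feature_dna(gb$sequence, f$location))
      if (grepl("*", aa, fixed = TRUE)) {
        warn_fmt("CDS %s: internal stop in conceptual translation; record flagged",
                 symbol)
        flagged <- TRUE
      }
    }
    out[[i]] <- data.frame(
      record_id = sprintf("%s_CDS%03d", gb$locus, i),
      gene_symbol = symbol, sequence = aa, length = nchar(aa),
      flagged = flagged, stringsAsFactors = FALSE)
  }
  prot <- rbind_rows(out, empty_protein_table())
  if (dedupe_genes) {
    prot <- prot[!duplicated(prot[, c("gene_symbol", "sequence")]), ,
                 drop = FALSE]
    rownames(prot) <- NULL
  }
  prot
}

empty_protein_table <- function() {
  data.frame(record_id = character(0), gene_symbol = character(0),
             sequence = character(0), length = integer(0),
             flagged = logical(0), stringsAsFactors = FALSE)
}

#' Read a protein FASTA with a gene-annotation table
#'
#' The annotation table maps FASTA record ids to gene symbols. Records whose
#' id is missing from the table are kept with the id itself as symbol, with
#' a warning; duplicated FASTA ids are an error.
#'
#' @param path protein multi-FASTA.
#' @param annotations optional TSV with columns `record_id`, `gene_symbol`.
#'   With `NULL`, every symbol is the FASTA id.
#' @return protein record data frame as in [read_genbank_proteins()].
#' @export
read_protein_fasta <- function(path, annotations = NULL) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_fmt("duplicated FASTA ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- sub("\\*$", "", toupper(as.character(aas)))
  symbols <- ids
  if (!is.null(annotations)) {
    ann <- utils::read.table(annotations, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("record_id", "gene_symbol") %in% names(ann))) {
      stop_fmt("annotation table needs 'record_id' and 'gene_symbol' columns")
    }
    hit <- match(ids, ann$record_id)
    if (anyNA(hit)) {
      warn_fmt("no annotation for id(s) %s; using the FASTA id as gene symbol",
               paste(ids[is.na(hit)], collapse = ", "))
    }
    symbols <- ifelse(is.na(hit), ids, ann$gene_symbol[hit])
  }
  data.frame(record_id = ids, gene_symbol = symbols, sequence = unname(seqs),
             length = nchar(unname(seqs)), flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Summarise a GenBank genome record
#'
#' @param path GenBank flat file.
#' @return list with `total_nt`, `gc_percent` (half-up, 1 decimal), and
#'   feature counts `n_pcg` (CDS), `n_trna`, `n_rrna`, `n_intron` (extra
#'   location segments across CDS/tRNA/rRNA features).
#' @export
summarize_genome <- function(path) {
  gb <- parse_genbank(path)
  n <- nchar(gb$sequence)
  gc <- sum(strsplit(gb$sequence, "")[[1]] %in% c("G", "C"))
  types <- vapply(gb$features, `[[`, character(1), "type")
  introns <- sum(vapply(gb$features, function(f) {
    if (f$type %in% c("CDS", "tRNA", "rRNA") && !is.null(f$location)) {
      nrow(f$location$segments) - 1L
    } else 0L
  }, integer(1)))
  list(total_nt = n,
       gc_percent = if (n > 0) round_half_up(100 * gc / n, 1) else NA_real_,
       n_pcg = sum(types == "CDS"),
       n_trna = sum(types == "tRNA"),
       n_rrna = sum(types == "rRNA"),
       n_intron = introns)
}

#' Write protein records to FASTA and an annotation TSV
#'
#' The FASTA/TSV pair round-trips through [read_protein_fasta()] with
#' identical sequences and symbols.
#'
#' @param proteins protein record data frame.
#' @param fasta_path,annotation_path output paths; either may be `NULL` to
#'   skip that file.
#' @return invisibly, the protein data frame.
#' @export
write_protein_fasta <- function(proteins, fasta_path, annotation_path = NULL) {
  if (!is.null(fasta_path)) {
    aas <- Biostrings::AAStringSet(proteins$sequence)
    names(aas) <- proteins$record_id
    Biostrings::writeXStringSet(aas, fasta_path, width = 60L)
  }
  if (!is.null(annotation_path)) {
    utils::write.table(
      proteins[, c("record_id", "gene_symbol", "length")],
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(proteins)
}

#' Total residue count of a protein set
#'
#' The denominator of every peptide-density statistic.
#'
#' @param proteins protein record data frame.
#' @return integer total number of residues.
#' @export
total_aa <- function(proteins) sum(proteins$length)
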