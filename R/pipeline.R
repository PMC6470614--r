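#' Run the full tripeptide screening pipeline
#'
#' End-to-end analysis over one or two annotated genomes: extract and
#' classify the proteome, profile amino-acid composition, IC50-filter the
#' peptide database, scan for tripeptide matches, tabulate by terminal
#' class under all three groupings, annotate digestive releasability, and
#' (when a second genome is given) compare the two proteomes. Every output
#' is TSV/JSON with a parameter header, plus a run manifest with input and
#' output checksums sufficient to re-run bit-identically. Any stage error
#' aborts the run and removes partial outputs.
#'
#' @param genome_a path to the primary genome (GenBank flat file) or
#'   protein FASTA (with `annotations_a`).
#' @param peptides path to the tripeptide activity table.
#' @param out_dir output directory, created if needed.
#' @param genome_b optional comparator genome.
#' @param annotations_a,annotations_b annotation TSVs when the genomes are
#'   protein FASTAs rather than GenBank records.
#' @param schema_path optional schema TSV; default is the packaged schema.
#' @param enzymes_path optional enzyme YAML; default [default_enzymes()].
#' @param ic50_max IC50 cutoff in uM (strict); default 20.
#' @param mode counting semantics, `"positions"` or `"unique_pairs"`.
#' @param dedupe_genes collapse identical (symbol, sequence) gene copies.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(genome_a, peptides, out_dir, genome_b = NULL,
                         annotations_a = NULL, annotations_b = NULL,
                         schema_path = NULL, enzymes_path = NULL,
                         ic50_max = 20, mode = "positions",
                         dedupe_genes = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  schema <- if (is.null(schema_path)) default_schema() else
    read_category_schema(schema_path)
  enzymes <- if (is.null(enzymes_path)) default_enzymes() else
    read_enzyme_config(enzymes_path)
  peps <- filter_by_ic50(load_peptide_table(peptides), ic50_max)

  load_proteome <- function(genome, annotations) {
    prot <- if (grepl("\\.(gb|gbk|genbank)$", genome, ignore.case = TRUE)) {
      read_genbank_proteins(genome, dedupe_genes = dedupe_genes)
    } else {
      read_protein_fasta(genome, annotations)
    }
    classify_proteins(prot, schema)
  }

  prot_a <- load_proteome(genome_a, annotations_a)
  comp <- composition(prot_a)
  utils::write.table(cbind(AA = rownames(format_composition(comp)),
                           format_composition(comp)),
                     emit("composition.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  hits_a <- scan_proteome(peps, prot_a, mode = mode)
  rel <- annotate_releasability(hits_a, prot_a, enzymes)
  utils::write.table(rel, emit("hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tables_a <- list()
  for (grouping in c("category", "photosystem_subcategory", "protein")) {
    tab <- tabulate_hits(hits_a, prot_a, grouping)
    tables_a[[grouping]] <- tab
    write_count_table(tab, emit(sprintf("counts_%s.tsv", grouping)))
  }

  if (!is.null(genome_b)) {
    prot_b <- load_proteome(genome_b, annotations_b)
    hits_b <- scan_proteome(peps, prot_b, mode = mode)
    cmpr <- compare_proteomes(tables_a$category,
                              tabulate_hits(hits_b, prot_b, "category"),
                              hits_a, hits_b)
    write_comparison(cmpr, emit("comparison.tsv"), emit("comparison.json"))
  }

  inputs <- c(genome_a = genome_a, genome_b = genome_b, peptides = peptides,
              annotations_a = annotations_a, annotations_b = annotations_b,
              schema = schema_path, enzymes = enzymes_path)
  manifest <- list(
    tool = "tripepscan",
    version = as.character(utils::packageVersion("tripepscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(ic50_max = ic50_max, mode = mode,
                      dedupe_genes = dedupe_genes,
                      schema = schema_path %||% "packaged default",
                      enzymes = enzymes_path %||% "packaged default"),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(stats::setNames(written, basename(written)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
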