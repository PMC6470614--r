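#' Read a gene functional-category schema
#'
#' The schema maps gene symbols to subcategories and subcategories to the
#' seven top-level categories (Genetic System, Ribosomal Proteins,
#' Photosystems, ATP Synthesis, Metabolism, Transport, Unknown). It is a
#' curation, not an algorithm, so it ships as an editable config; users
#' screening other genomes supply their own.
#'
#' @param path TSV with header columns `gene`, `subcategory`, `category`.
#' @return schema data frame (validated).
#' @seealso [default_schema()], [validate_schema()]
#' @export
read_category_schema <- function(path) {
  schema <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "#")
  if (!all(c("gene", "subcategory", "category") %in% names(schema))) {
    stop_fmt("schema needs 'gene', 'subcategory', 'category' columns")
  }
  rep <- validate_schema(schema)
  if (!rep$valid) stop_fmt("invalid schema: %s", paste(rep$problems, collapse = "; "))
  schema
}

#' The packaged plastid gene schema
#'
#' 205 protein-coding gene symbols of a red-algal (dulse) plastid genome,
#' curated into 7 categories and 23 subcategories. psbH is assigned to
#' Photosystem II only.
#'
#' @return schema data frame with 205 rows.
#' @export
default_schema <- function() {
  read_category_schema(system.file("extdata", "plastid_gene_schema.tsv",
                                   package = "tripepscan", mustWork = TRUE))
}

#' Validate a category schema
#'
#' Reports duplicate gene symbols (an error condition: classification must
#' be unambiguous), subcategories mapped to more than one category, and the
#' per-subcategory gene tally for comparison against a published schema.
#'
#' @param schema schema data frame.
#' @return list with `valid`, `n_genes`, `problems` (character) and
#'   `tally` (subcategory-level gene counts).
#' @export
validate_schema <- function(schema) {
  problems <- character(0)
  lower <- tolower(schema$gene)
  dup <- unique(schema$gene[lower %in% lower[duplicated(lower)]])
  if (length(dup)) {
    problems <- c(problems, sprintf("gene symbol(s) in more than one subcategory: %s",
                                    paste(dup, collapse = ", ")))
  }
  sub2cat <- unique(schema[, c("subcategory", "category")])
  multi <- sub2cat$subcategory[duplicated(sub2cat$subcategory)]
  if (length(multi)) {
    problems <- c(problems, sprintf("subcategory mapped to several categories: %s",
                                    paste(unique(multi), collapse = ", ")))
  }
  unknown_cat <- setdiff(unique(schema$category), CATEGORIES)
  if (length(unknown_cat)) {
    problems <- c(problems, sprintf("category outside the 7-label set: %s",
                                    paste(unknown_cat, collapse = ", ")))
  }
  tally <- if (nrow(schema)) {
    as.data.frame(table(subcategory = schema$subcategory),
                  responseName = "n_genes", stringsAsFactors = FALSE)
  } else {
    data.frame(subcategory = character(0), n_genes = integer(0))
  }
  list(valid = length(problems) == 0L, n_genes = nrow(schema),
       problems = problems, tally = tally)
}

#' Attach functional categories to protein records
#'
#' Gene-symbol matching is case-insensitive (annotation qualifier casing
#' varies between deposits). Symbols absent from the schema fall back to
#' category "Unknown", subcategory "Unique ORFs", with one summary warning —
#' classification is total, every protein gets a label.
#'
#' @param proteins protein record data frame.
#' @param schema schema data frame; default [default_schema()].
#' @return the protein data frame with `category` and `subcategory` columns.
#' @export
classify_proteins <- function(proteins, schema = default_schema()) {
  hit <- match(tolower(proteins$gene_symbol), tolower(schema$gene))
  if (anyNA(hit)) {
    warn_fmt("%d gene symbol(s) not in schema, classified Unknown/Unique ORFs: %s",
             sum(is.na(hit)),
             paste(unique(proteins$gene_symbol[is.na(hit)]), collapse = ", "))
  }
  proteins$category <- ifelse(is.na(hit), "Unknown", schema$category[hit])
  proteins$subcategory <- ifelse(is.na(hit), "Unique ORFs", schema$subcategory[hit])
  proteins
}
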