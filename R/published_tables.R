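# Loaders for the packaged literature tables: the published tripeptide
# count tables and amino-acid composition of the study proteomes. These are
# reference values shipped for arithmetic cross-checks and comparisons;
# nothing in them is computed by this package.

#' Load a published tripeptide count table
#'
#' @param name `"palmaria_sp"` (study proteome, category grouping),
#'   `"p_palmata"` (comparator proteome), or `"photosystems"` (photosystem
#'   subcategory grouping of the study proteome).
#' @return list with `counts` (12 class rows x group columns, integer),
#'   `database` (peptides per class in the screened database, or `NULL`),
#'   `printed_total` (per-group totals as printed), `total_aa`,
#'   `printed_density` (the printed "Peptide/AA (%)" row).
#' @export
published_count_table <- function(name = c("palmaria_sp", "p_palmata",
                                           "photosystems")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      sprintf("published_counts_%s.tsv", name),
                      package = "tripepscan", mustWork = TRUE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(raw) <- raw$class
  raw$class <- NULL
  db <- NULL
  if ("database" %in% names(raw)) {
    db <- stats::setNames(as.integer(raw[TERMINAL_CLASSES, "database"]),
                          TERMINAL_CLASSES)
    raw$database <- NULL
  }
  list(counts = as.matrix(raw[TERMINAL_CLASSES, , drop = FALSE]),
       database = db,
       printed_total = unlist(raw["Total", ]),
       total_aa = unlist(raw["Total_AA", ]),
       printed_density = unlist(raw["Peptide_AA_pct", ]))
}

#' Load the published amino-acid composition table
#'
#' Percent residue composition of the study plastid proteome per functional
#' category, plus wet-lab proximate reference columns for the comparator
#' species (`ref_total_aa`, `ref_protein`; Asp and Glu rows there stand for
#' Asx/Glx, since acid hydrolysis deamidates).
#'
#' @return data frame: one row per amino acid (display names, cysteine as
#'   "Cystine") plus a `Total_AA` row of residue counts.
#' @export
published_aa_composition <- function() {
  path <- system.file("extdata", "published_aa_composition.tsv",
                      package = "tripepscan", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' The packaged example peptide table
#'
#' Ten tripeptides: the four published catch-all-class (XXX) peptides and
#' six synthetic fillers. For tests and demonstrations.
#'
#' @return peptide table as from [load_peptide_table()].
#' @export
example_peptide_table <- function() {
  load_peptide_table(system.file("extdata", "peptides_example.tsv",
                                 package = "tripepscan", mustWork = TRUE))
}
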