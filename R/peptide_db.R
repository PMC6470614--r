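#' Load a tripeptide activity table
#'
#' Reads a TSV/CSV of ACE-inhibitory tripeptides with their IC50 values, the
#' shape of an export from a curated bioactive-peptide database. Only
#' tripeptides are accepted: longer or shorter sequences are treated as input
#' errors rather than silently dropped, so that database hygiene problems
#' surface. Duplicate sequences (the same peptide reported from several
#' protein sources) are collapsed to the single most potent entry (minimum
#' IC50) with a warning.
#'
#' @param path path to a delimited file with header columns `sequence`,
#'   `ic50_uM` and optionally `source`. Tab- and comma-separated files are
#'   both accepted (sniffed from the header line).
#' @return a data frame with columns `sequence`, `ic50_uM`, `source` and
#'   `terminal_class`, one row per distinct peptide.
#' @seealso [filter_by_ic50()], [terminal_class()]
#' @export
load_peptide_table <- function(path) {
  if (!file.exists(path)) stop_fmt("peptide table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    return(empty_peptide_table())
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "#", strip.white = TRUE,
                           colClasses = "character")
  if (!all(c("sequence", "ic50_uM") %in% names(tab))) {
    stop_fmt("peptide table must have 'sequence' and 'ic50_uM' columns; found: %s",
             paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) == 0L) return(empty_peptide_table())
  if (!"source" %in% names(tab)) tab$source <- NA_character_

  seqs <- toupper(tab$sequence)
  ic50 <- suppressWarnings(as.numeric(tab$ic50_uM))
  for (i in seq_len(nrow(tab))) {
    if (is.na(ic50[i]) || ic50[i] <= 0) {
      stop_fmt("row %d: ic50_uM must be a positive number, got '%s'",
               i, tab$ic50_uM[i])
    }
    if (!is_valid_tripeptide(seqs[i])) {
      stop_fmt(paste0("row %d: '%s' is not a tripeptide over the 20 standard ",
                      "amino acids (only tripeptides are in scope)"),
               i, tab$sequence[i])
    }
  }

  if (anyDuplicated(seqs)) {
    dups <- unique(seqs[duplicated(seqs)])
    warn_fmt("collapsing %d duplicated peptide sequence(s) to minimum IC50: %s",
             length(dups), paste(dups, collapse = ", "))
    keep <- unlist(lapply(split(seq_along(seqs), seqs)[unique(seqs)],
                          function(idx) idx[which.min(ic50[idx])]))
    keep <- sort(keep)
    seqs <- seqs[keep]; ic50 <- ic50[keep]; tab <- tab[keep, , drop = FALSE]
  }

  data.frame(sequence = seqs,
             ic50_uM = ic50,
             source = tab$source,
             terminal_class = vapply(seqs, terminal_class, character(1),
                                     USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

empty_peptide_table <- function() {
  data.frame(sequence = character(0), ic50_uM = numeric(0),
             source = character(0), terminal_class = character(0),
             stringsAsFactors = FALSE)
}

#' Filter peptides by IC50 potency
#'
#' Keeps peptides with IC50 strictly below `threshold` (in micromolar), the
#' "more potent than" selection rule. The comparison is strict: a peptide at
#' exactly the threshold is excluded. Input order is preserved and the
#' operation is idempotent.
#'
#' @param peptides peptide table from [load_peptide_table()].
#' @param threshold positive IC50 cutoff in uM; default 20.
#' @return the filtered peptide table.
#' @export
filter_by_ic50 <- function(peptides, threshold = 20) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  peptides[peptides$ic50_uM < threshold, , drop = FALSE]
}

#' C-terminal class of a tripeptide
#'
#' Tripeptides are grouped by their C-terminal residue: termini P, Y, A, L,
#' W, G, R, V, F, K and N each define a class (`XXP`, `XXY`, ...); any other
#' terminus falls into the catch-all class `XXX`. Every valid tripeptide maps
#' to exactly one of the 12 classes.
#'
#' @param sequence a tripeptide string (vectorised).
#' @return character vector of class labels.
#' @examples
#' terminal_class("IPP")  # "XXP"
#' terminal_class("LVQ")  # "XXX"
#' @export
terminal_class <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- !is_valid_tripeptide(sequence)
  if (any(bad)) {
    stop_fmt("not a valid tripeptide: %s",
             paste(sequence[bad], collapse = ", "))
  }
  last <- substr(sequence, 3L, 3L)
  ifelse(last %in% TERMINAL_RESIDUES, paste0("XX", last), "XXX")
}
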