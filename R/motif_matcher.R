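#' Count occurrences of a tripeptide in a protein sequence
#'
#' Counts every start offset at which the tripeptide occurs; overlapping
#' occurrences all count (a match at offset i never masks one at i+1).
#' Windows containing any non-standard residue never match.
#'
#' @param peptide tripeptide string.
#' @param sequence amino-acid string.
#' @return integer occurrence count.
#' @examples
#' count_occurrences("AAA", "AAAA")  # 2 (overlap counted)
#' @export
count_occurrences <- function(peptide, sequence) {
  length(match_positions(peptide, sequence))
}

# 0-based start offsets of (possibly overlapping) exact tripeptide matches.
match_positions <- function(peptide, sequence) {
  if (!is_valid_tripeptide(toupper(peptide))) {
    stop_fmt("not a valid tripeptide: '%s'", peptide)
  }
  n <- nchar(sequence)
  if (n < 3L) return(integer(0))
  starts <- seq_len(n - 2L)
  which(substring(sequence, starts, starts + 2L) == toupper(peptide)) - 1L
}

#' Scan a proteome for database tripeptides
#'
#' The pipeline's core computation: every protein is compared against every
#' peptide in the (filtered) activity database and each occurrence is
#' recorded as a hit. Two counting semantics are supported:
#' `mode = "positions"` (default) records every positional occurrence —
#' each one a potential released peptide; `mode = "unique_pairs"` collapses
#' to one hit per (peptide, protein) pair, kept at the first position.
#' Output order is deterministic: by protein (input order), then position,
#' then peptide.
#'
#' @param peptides peptide table (see [load_peptide_table()]), already
#'   IC50-filtered.
#' @param proteins classified protein record data frame.
#' @param mode `"positions"` or `"unique_pairs"`.
#' @return data frame of hits: `peptide`, `record_id`, `gene_symbol`,
#'   `position` (0-based start offset), `terminal_class`, plus `category`
#'   and `subcategory` when the proteins carry them. Attribute `mode`
#'   records the counting semantics.
#' @export
scan_proteome <- function(peptides, proteins, mode = c("positions", "unique_pairs")) {
  mode <- match.arg(mode)
  classified <- all(c("category", "subcategory") %in% names(proteins))
  out <- vector("list", nrow(proteins))
  pep_class <- stats::setNames(peptides$terminal_class, peptides$sequence)
  for (i in seq_len(nrow(proteins))) {
    seq_i <- proteins$sequence[i]
    n <- nchar(seq_i)
    if (n < 3L || nrow(peptides) == 0L) next
    starts <- seq_len(n - 2L)
    windows <- substring(seq_i, starts, starts + 2L)
    sel <- which(windows %in% peptides$sequence)
    if (!length(sel)) next
    hit <- data.frame(peptide = windows[sel],
                      record_id = proteins$record_id[i],
                      gene_symbol = proteins$gene_symbol[i],
                      position = sel - 1L,
                      stringsAsFactors = FALSE)
    hit <- hit[order(hit$position, hit$peptide), , drop = FALSE]
    if (mode == "unique_pairs") {
      hit <- hit[!duplicated(hit$peptide), , drop = FALSE]
    }
    out[[i]] <- hit
  }
  hits <- rbind_rows(out, data.frame(peptide = character(0),
                                     record_id = character(0),
                                     gene_symbol = character(0),
                                     position = integer(0),
                                     stringsAsFactors = FALSE))
  hits$terminal_class <- unname(pep_class[hits$peptide])
  if (classified) {
    at <- match(hits$record_id, proteins$record_id)
    hits$category <- proteins$category[at]
    hits$subcategory <- proteins$subcategory[at]
  }
  attr(hits, "mode") <- mode
  hits
}

#' Tabulate hits by terminal class and group
#'
#' Builds the class-by-group count structure: 12 terminal-class rows against
#' a grouping of the proteome — the 7 functional categories, the 5
#' photosystem subcategories, or individual proteins (gene symbols). Each
#' group's residue total ("Total AA") sums over every protein in the group,
#' matched or not, and the peptide density is 100 * matches / Total AA.
#'
#' @param hits hit data frame from [scan_proteome()].
#' @param proteins the classified protein records the hits were produced
#'   from (needed for group residue totals).
#' @param grouping `"category"`, `"photosystem_subcategory"`, or
#'   `"protein"`.
#' @return object of class `count_table`: list with `counts` (12 x groups
#'   integer matrix), `peptide_total` and `total_aa` (named vectors per
#'   group), `density` (half-up, 2 decimals), `grand_total`, `grouping`,
#'   `mode`.
#' @export
tabulate_hits <- function(hits, proteins,
                          grouping = c("category", "photosystem_subcategory",
                                       "protein")) {
  grouping <- match.arg(grouping)
  if (!all(c("category", "subcategory") %in% names(proteins))) {
    stop_fmt("proteins must be classified before tabulation")
  }
  if (grouping == "category") {
    groups <- CATEGORIES
    pgroup <- proteins$category
    hgroup <- hits$category
  } else if (grouping == "photosystem_subcategory") {
    keep_p <- proteins$category == "Photosystems"
    if (!any(keep_p)) warn_fmt("no Photosystems proteins; table is empty")
    groups <- PS_SUBCATEGORIES
    pgroup <- ifelse(keep_p, proteins$subcategory, NA)
    hgroup <- ifelse(hits$category == "Photosystems", hits$subcategory, NA)
  } else {
    groups <- unique(proteins$gene_symbol)
    pgroup <- proteins$gene_symbol
    hgroup <- hits$gene_symbol
  }
  counts <- matrix(0L, nrow = length(TERMINAL_CLASSES), ncol = length(groups),
                   dimnames = list(TERMINAL_CLASSES, groups))
  keep <- !is.na(hgroup)
  if (any(keep)) {
    tab <- table(factor(hits$terminal_class[keep], levels = TERMINAL_CLASSES),
                 factor(hgroup[keep], levels = groups))
    counts[] <- as.integer(tab)
  }
  taa <- vapply(groups, function(g)
    sum(proteins$length[!is.na(pgroup) & pgroup == g]), numeric(1))
  ptot <- colSums(counts)
  dens <- ifelse(taa > 0, round_half_up(100 * ptot / pmax(taa, 1), 2), 0)
  structure(list(counts = counts, peptide_total = ptot, total_aa = taa,
                 density = dens, grand_total = sum(ptot), grouping = grouping,
                 mode = attr(hits, "mode")),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Tripeptide count table (grouping = ", x$grouping,
      if (!is.null(x$mode)) paste0(", mode = ", x$mode), ")\n", sep = "")
  out <- rbind(x$counts, Total = x$peptide_total, Total_AA = x$total_aa,
               `Peptide/AA (%)` = sprintf("%.2f", x$density))
  print(out, quote = FALSE, ...)
  cat("Grand total:", x$grand_total, "\n")
  invisible(x)
}

#' Peptide density per hundred residues
#'
#' The enrichment statistic printed as "Peptide/AA (%)": 100 * matches /
#' total residues, rounded half-up to 2 decimals.
#'
#' @param match_count number of peptide matches in a group.
#' @param total_aa residue total of the group; must be positive.
#' @return density in percent (vectorised).
#' @examples
#' peptide_density(751, 50333)  # 1.49
#' @export
peptide_density <- function(match_count, total_aa) {
  if (any(total_aa <= 0)) stop_fmt("total_aa must be positive")
  round_half_up(100 * match_count / total_aa, 2)
}

#' Write a count table as TSV
#'
#' Class rows, then `Total`, `Total_AA` and `Peptide/AA (%)` rows, mirroring
#' the published table layout; a header comment records grouping and mode.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return invisibly, `x`.
#' @export
write_count_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tripepscan count table; grouping=%s; mode=%s",
                     x$grouping, x$mode %||% "NA"), con)
  body <- data.frame(Peptide = c(rownames(x$counts), "Total", "Total_AA",
                                 "Peptide/AA (%)"),
                     rbind(x$counts, x$peptide_total, x$total_aa,
                           sprintf("%.2f", x$density)),
                     check.names = FALSE)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
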