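#' Amino-acid composition per functional group
#'
#' Tallies the 20 standard residues over the whole protein set and within
#' each functional category, as residue counts and percentages. Percentages
#' are kept at full precision internally; [format_composition()] applies the
#' half-up 1-decimal display rounding. Non-standard residues (B, Z, X, U, O,
#' ...) are excluded from the 20-residue tally, counted in an `other`
#' bucket, and warned about.
#'
#' @param proteins classified protein record data frame (see
#'   [classify_proteins()]); an unclassified set is treated as one group.
#' @return object of class `composition_table`: list with `counts` (21 x
#'   groups matrix, rows = 20 AAs + "other"), `percent` (20 x groups, % of
#'   standard residues, unrounded), `total_aa` (named vector, standard
#'   residues per group), `groups`.
#' @export
composition <- function(proteins) {
  groups <- "Plastid"
  membership <- list(Plastid = seq_len(nrow(proteins)))
  if ("category" %in% names(proteins)) {
    for (cat in CATEGORIES) membership[[cat]] <- which(proteins$category == cat)
    groups <- c(groups, CATEGORIES)
  }
  counts <- matrix(0L, nrow = 21L, ncol = length(groups),
                   dimnames = list(c(AA_STANDARD, "other"), groups))
  for (g in groups) {
    seqs <- proteins$sequence[membership[[g]]]
    if (!length(seqs)) next
    tab <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
    std <- intersect(names(tab), AA_STANDARD)
    counts[std, g] <- as.integer(tab[std])
    counts["other", g] <- sum(tab) - sum(tab[std])
  }
  if (counts["other", "Plastid"] > 0) {
    warn_fmt("%d non-standard residue(s) excluded from the 20-AA tally",
             counts["other", "Plastid"])
  }
  tot <- colSums(counts[AA_STANDARD, , drop = FALSE])
  percent <- sweep(counts[AA_STANDARD, , drop = FALSE], 2L,
                   pmax(tot, 1L), "/") * 100
  structure(list(counts = counts, percent = percent, total_aa = tot,
                 groups = groups),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Amino-acid composition (", length(x$groups), " group(s), ",
      x$total_aa[["Plastid"]], " residues total)\n", sep = "")
  print(format_composition(x), ...)
  invisible(x)
}

#' Display-rounded composition table
#'
#' @param comp a `composition_table`.
#' @return data frame mirroring the published layout: 20 AA rows (cysteine
#'   labelled "Cystine" for display) with percentages rounded half-up to 1
#'   decimal, plus a `Total_AA` row of residue counts.
#' @export
format_composition <- function(comp) {
  pct <- round_half_up(comp$percent, 1)
  display_names <- c(A = "Alanine", R = "Arginine", D = "Aspartic acid",
                     N = "Asparagine", C = "Cystine", E = "Glutamic acid",
                     Q = "Glutamine", G = "Glycine", H = "Histidine",
                     I = "Isoleucine", L = "Leucine", K = "Lysine",
                     M = "Methionine", F = "Phenylalanine", P = "Proline",
                     S = "Serine", T = "Threonine", W = "Tryptophan",
                     Y = "Tyrosine", V = "Valine")
  ord <- names(display_names)
  out <- as.data.frame(rbind(pct[ord, , drop = FALSE],
                             Total_AA = comp$total_aa))
  rownames(out) <- c(unname(display_names), "Total_AA")
  out
}

#' Compare a computed composition against a reference
#'
#' Signed differences, in percentage points, between a computed group column
#' and a reference composition (e.g. wet-lab proximate amino-acid analysis).
#' Because acid hydrolysis deamidates, proximate analysis reports Asx and
#' Glx; `combine = TRUE` pools D+N and E+Q on the computed side before
#' differencing whenever the reference lacks separate N/Q entries.
#'
#' @param comp a `composition_table`.
#' @param reference named numeric vector of reference percentages, names
#'   either one-letter codes or the combined labels `DN`/`EQ`.
#' @param group which computed group to compare; default "Plastid".
#' @param combine pool D+N and E+Q when the reference does. Default `TRUE`.
#' @return data frame with `computed`, `reference`, `difference` (computed -
#'   reference, percentage points), one row per reference entry.
#' @export
compare_composition <- function(comp, reference, group = "Plastid",
                                combine = TRUE) {
  pct <- comp$percent[, group]
  vals <- c(as.list(pct),
            DN = unname(pct["D"] + pct["N"]),
            EQ = unname(pct["E"] + pct["Q"]))
  if (combine && !("N" %in% names(reference)) && "D" %in% names(reference)) {
    names(reference)[names(reference) == "D"] <- "DN"
  }
  if (combine && !("Q" %in% names(reference)) && "E" %in% names(reference)) {
    names(reference)[names(reference) == "E"] <- "EQ"
  }
  bad <- setdiff(names(reference), names(vals))
  if (length(bad)) stop_fmt("unknown reference entries: %s", paste(bad, collapse = ", "))
  computed <- unlist(vals[names(reference)])
  data.frame(aa = names(reference), computed = computed,
             reference = unname(reference),
             difference = computed - unname(reference),
             row.names = NULL, stringsAsFactors = FALSE)
}
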