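#' Default digestive-protease C-terminal specificities
#'
#' The four gastrointestinal/processing proteases whose preferred P1
#' residues bracket ACE-inhibitory tripeptides in digests: pepsin (cleaves
#' after D, E, L, F, W, Y), chymotrypsin (F, W, Y), elastase (A, G, I, L, S,
#' V) and prolyl endopeptidase (P). A binary site model: pH, kinetics and
#' missed cleavages are out of scope.
#'
#' @return named list of character vectors, one set of cleavable C-terminal
#'   residues per enzyme.
#' @export
default_enzymes <- function() {
  list(
    pepsin = c("D", "E", "L", "F", "W", "Y"),
    chymotrypsin = c("F", "W", "Y"),
    elastase = c("A", "G", "I", "L", "S", "V"),
    `prolyl endopeptidase` = c("P")
  )
}

#' Read an enzyme specificity config
#'
#' YAML list of `{name, c_term_residues}` entries, so users can add e.g.
#' trypsin or thermolysin.
#'
#' @param path YAML file.
#' @return named list as in [default_enzymes()].
#' @export
read_enzyme_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (e in raw) {
    vals <- as.character(unlist(e$c_term_residues))
    # unquoted Y/N in YAML 1.1 decode as logicals; map them back to residues
    vals[vals == "TRUE"] <- "Y"
    vals[vals == "FALSE"] <- "N"
    res <- toupper(vals)
    if (is.null(e$name) || !length(res)) {
      stop_fmt("each enzyme entry needs 'name' and non-empty 'c_term_residues'")
    }
    if (!all(res %in% AA_STANDARD)) {
      stop_fmt("enzyme %s: residues outside the 20 standard AAs: %s",
               e$name, paste(setdiff(res, AA_STANDARD), collapse = ", "))
    }
    out[[e$name]] <- res
  }
  out
}

#' Annotate matched peptides with in-silico releasability
#'
#' A matched tripeptide can only be liberated by digestion if proteolysis
#' can create both of its boundaries. The C-boundary follows the enzymes'
#' C-terminal specificities: the hit is C-releasable by every enzyme whose
#' residue set contains the hit's last residue. The N-boundary rule is this
#' package's minimal model extension: the boundary is cleavable when the
#' hit starts at the protein N-terminus or the residue immediately
#' preceding the hit is cleavable by any configured enzyme. A hit is fully
#' releasable when both hold. No P1' exclusion rules (e.g. proline blocking)
#' are applied.
#'
#' @param hits hit data frame from [scan_proteome()].
#' @param proteins the protein records the hits reference.
#' @param enzymes named list of C-terminal residue sets; default
#'   [default_enzymes()].
#' @return the hit data frame with columns `c_releasable_by`
#'   (semicolon-joined enzyme names, "" when none), `n_boundary_cleavable`
#'   and `fully_releasable`.
#' @export
annotate_releasability <- function(hits, proteins, enzymes = default_enzymes()) {
  at <- match(hits$record_id, proteins$record_id)
  if (anyNA(at)) {
    stop_fmt("hit(s) reference unknown protein record(s): %s",
             paste(unique(hits$record_id[is.na(at)]), collapse = ", "))
  }
  if (nrow(hits) && any(hits$position + 3L > proteins$length[at])) {
    stop_fmt("hit position(s) outside the protein sequence")
  }
  all_residues <- unique(unlist(enzymes))
  last <- substr(hits$peptide, 3L, 3L)
  crel <- vapply(last, function(r) {
    paste(names(enzymes)[vapply(enzymes, function(s) r %in% s, logical(1))],
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  prev <- ifelse(hits$position == 0L, "",
                 substr(proteins$sequence[at], hits$position, hits$position))
  nok <- hits$position == 0L | prev %in% all_residues
  if (!nrow(hits)) nok <- logical(0)
  hits$c_releasable_by <- crel
  hits$n_boundary_cleavable <- nok
  hits$fully_releasable <- nzchar(crel) & nok
  hits
}
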