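#' Compare tripeptide screens of two proteomes
#'
#' Side-by-side comparison of two count tables built with the same grouping
#' and counting mode: a cell-wise delta matrix plus the shared and unique
#' (peptide, gene) pair sets. Peptide sets key on sequence and gene symbol,
#' not position, because orthologous proteins differ in length; this is what
#' lets the report distinguish "same counts, different peptides".
#'
#' @param table_a,table_b `count_table` objects (see [tabulate_hits()]).
#' @param hits_a,hits_b the hit data frames the tables were built from.
#' @return object of class `proteome_comparison`: list with `table_a`,
#'   `table_b`, `delta` (a - b, integer matrix over the union of groups),
#'   `delta_total`, `shared`, `only_a`, `only_b` (sorted data frames of
#'   peptide/gene pairs).
#' @export
compare_proteomes <- function(table_a, table_b, hits_a, hits_b) {
  if (!identical(table_a$grouping, table_b$grouping)) {
    stop_fmt("tables use different groupings (%s vs %s); comparison would be meaningless",
             table_a$grouping, table_b$grouping)
  }
  ma <- attr(hits_a, "mode") %||% table_a$mode
  mb <- attr(hits_b, "mode") %||% table_b$mode
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb)) {
    stop_fmt("tables use different counting modes (%s vs %s)", ma, mb)
  }
  groups <- union(colnames(table_a$counts), colnames(table_b$counts))
  pad <- function(m) {
    out <- matrix(0L, nrow = length(TERMINAL_CLASSES), ncol = length(groups),
                  dimnames = list(TERMINAL_CLASSES, groups))
    out[, colnames(m)] <- m
    out
  }
  delta <- pad(table_a$counts) - pad(table_b$counts)

  pair_key <- function(h) {
    if (!nrow(h)) return(character(0))
    sort(unique(paste(h$peptide, h$gene_symbol, sep = "\t")))
  }
  ka <- pair_key(hits_a); kb <- pair_key(hits_b)
  unkey <- function(k) {
    if (!length(k)) {
      return(data.frame(peptide = character(0), gene_symbol = character(0),
                        stringsAsFactors = FALSE))
    }
    parts <- do.call(rbind, strsplit(k, "\t", fixed = TRUE))
    data.frame(peptide = parts[, 1], gene_symbol = parts[, 2],
               stringsAsFactors = FALSE)
  }
  structure(list(table_a = table_a, table_b = table_b, delta = delta,
                 delta_total = table_a$grand_total - table_b$grand_total,
                 shared = unkey(intersect(ka, kb)),
                 only_a = unkey(setdiff(ka, kb)),
                 only_b = unkey(setdiff(kb, ka))),
            class = "proteome_comparison")
}

#' @export
print.proteome_comparison <- function(x, ...) {
  cat("Proteome comparison (grouping =", x$table_a$grouping, ")\n")
  cat("Grand totals:", x$table_a$grand_total, "vs", x$table_b$grand_total,
      sprintf("(delta %+d)\n", x$delta_total))
  cat("Per-group peptide deltas (a - b):\n")
  print(colSums(x$delta))
  cat(sprintf("Peptide-gene pairs: %d shared, %d only in a, %d only in b\n",
              nrow(x$shared), nrow(x$only_a), nrow(x$only_b)))
  invisible(x)
}

#' Write a comparison report
#'
#' Emits a side-by-side TSV (class rows x group columns for a, b and delta)
#' and a JSON set-difference report. The set-difference section is always
#' written, even when empty, so "same counts, different peptides" is visible.
#'
#' @param x a `proteome_comparison`.
#' @param tsv_path,json_path output paths (`NULL` skips).
#' @return invisibly, `x`.
#' @export
write_comparison <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    groups <- colnames(x$delta)
    blocks <- lapply(groups, function(g) {
      a <- if (g %in% colnames(x$table_a$counts)) x$table_a$counts[, g] else 0L
      b <- if (g %in% colnames(x$table_b$counts)) x$table_b$counts[, g] else 0L
      out <- cbind(a, b, x$delta[, g])
      colnames(out) <- paste0(g, c(" (a)", " (b)", " (delta)"))
      out
    })
    body <- data.frame(Peptide = TERMINAL_CLASSES, do.call(cbind, blocks),
                       check.names = FALSE)
    con <- file(tsv_path, "w")
    writeLines(sprintf("# tripepscan comparison; grouping=%s", x$table_a$grouping), con)
    utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(delta_total = x$delta_total,
           shared = x$shared, only_a = x$only_a, only_b = x$only_b),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}
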