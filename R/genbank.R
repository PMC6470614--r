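# Minimal GenBank flat-file reader.
#
# Parses the LOCUS line, the feature table (keys, locations, qualifiers) and
# the ORIGIN sequence block of a single-record flat file. Coverage is the
# subset of the format an annotated organellar genome uses: simple ranges,
# join()/order() of ranges, complement() at the top level or per segment,
# and partial-end markers (< >), which are stripped. Coordinates are
# converted from GenBank 1-based inclusive to 0-based half-open at this
# boundary and nowhere else.

parse_genbank <- function(path) {
  if (!file.exists(path)) stop_fmt("GenBank file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop_fmt("not a GenBank flat file (no LOCUS line): %s", path)
  }
  locus <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[1])), "\\s+")[[1]][1]

  feat_start <- grep("^FEATURES", lines)[1]
  origin <- grep("^ORIGIN", lines)[1]
  terminator <- grep("^//", lines)[1]
  if (is.na(origin)) stop_fmt("GenBank file has no ORIGIN block: %s", path)
  if (is.na(terminator)) terminator <- length(lines) + 1L

  seq_lines <- lines[(origin + 1L):(terminator - 1L)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (!is.na(feat_start)) {
    flines <- lines[(feat_start + 1L):(origin - 1L)]
    cur <- NULL
    for (ln in flines) {
      if (grepl("^ {5}\\S", ln)) {               # new feature key at col 6
        if (!is.null(cur)) features[[length(features) + 1L]] <- finish_feature(cur)
        m <- regmatches(ln, regexec("^ {5}(\\S+)\\s+(\\S.*)$", ln))[[1]]
        if (length(m) < 3L) stop_fmt("malformed feature line: '%s'", ln)
        cur <- list(type = m[2], location = m[3], qual_lines = character(0))
      } else if (!is.null(cur)) {
        body <- trimws(ln)
        if (!nzchar(body)) next
        if (startsWith(body, "/")) {
          cur$qual_lines <- c(cur$qual_lines, body)
        } else if (length(cur$qual_lines)) {     # qualifier continuation
          n <- length(cur$qual_lines)
          joiner <- if (grepl("^/translation=", cur$qual_lines[n])) "" else " "
          cur$qual_lines[n] <- paste0(cur$qual_lines[n], joiner, body)
        } else {                                 # location continuation
          cur$location <- paste0(cur$location, body)
        }
      }
    }
    if (!is.null(cur)) features[[length(features) + 1L]] <- finish_feature(cur)
  }

  list(locus = locus, sequence = sequence, features = features)
}

finish_feature <- function(cur) {
  quals <- list()
  for (q in cur$qual_lines) {
    m <- regmatches(q, regexec('^/([A-Za-z0-9_]+)(=(.*))?$', q))[[1]]
    key <- m[2]
    val <- if (nchar(m[3])) gsub('^"|"$', "", m[4]) else TRUE
    quals[[key]] <- val
  }
  loc <- tryCatch(parse_location(cur$location), error = function(e) NULL)
  list(type = cur$type, location_text = cur$location, location = loc,
       qualifiers = quals)
}

# Returns list(complement = flag, segments = data.frame(start, end, complement))
# with 0-based half-open segment coordinates in genome order.
parse_location <- function(text) {
  text <- gsub("[<>[:space:]]", "", text)
  top_comp <- FALSE
  if (grepl("^complement\\(.*\\)$", text)) {
    top_comp <- TRUE
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  if (grepl("^(join|order)\\(.*\\)$", text)) {
    text <- sub("^(join|order)\\((.*)\\)$", "\\2", text)
  }
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    comp <- FALSE
    if (grepl("^complement\\(.*\\)$", p)) {
      comp <- TRUE
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else {
      stop_fmt("unsupported location segment: '%s'", p)
    }
    data.frame(start = ab[1] - 1L, end = ab[2], complement = comp)
  })
  list(complement = top_comp, segments = do.call(rbind, segs))
}

# Nucleotide sequence of a feature, spliced and strand-corrected.
feature_dna <- function(genome_seq, loc) {
  pieces <- vapply(seq_len(nrow(loc$segments)), function(i) {
    s <- loc$segments[i, ]
    piece <- substr(genome_seq, s$start + 1L, s$end)
    if (s$complement) {
      piece <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
    }
    piece
  }, character(1))
  dna <- paste(pieces, collapse = "")
  if (loc$complement) {
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  }
  dna
}

# Conceptual translation of a CDS under the bacterial/plastid genetic code
# (NCBI table 11); trailing stop removed. Codons are translated literally —
# no initiator-codon remapping to Met — because deposited /translation
# qualifiers, which real records carry, are authoritative anyway, and a
# literal translation round-trips synthetic fixtures exactly.
translate_cds <- function(dna) {
  if (nchar(dna) %% 3L != 0L) {
    warn_fmt("CDS length %d is not a multiple of 3; truncating", nchar(dna))
    dna <- substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}
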