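#' @keywords internal
"_PACKAGE"

# The 20 standard amino-acid one-letter codes, the only residues that take
# part in composition tallies and motif matching.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# C-terminal residues with a class of their own; every other terminus falls
# into the catch-all class XXX. Order fixes row order in all count tables.
TERMINAL_RESIDUES <- c("P", "Y", "A", "L", "W", "G", "R", "V", "F", "K", "N")
TERMINAL_CLASSES <- c(paste0("XX", TERMINAL_RESIDUES), "XXX")

# The seven functional categories, in display order.
CATEGORIES <- c("Genetic System", "Ribosomal Proteins", "Photosystems",
                "ATP Synthesis", "Metabolism", "Transport", "Unknown")

# The five photosystem subcategories, in display order.
PS_SUBCATEGORIES <- c("Phycobilisomes", "Photosystem I", "Photosystem II",
                      "Cytochrome complex", "Redox system")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals, as used for
#' every displayed percentage. Base [round()] rounds half to even, which would
#' turn 0.125 into 0.12; tabulated percentages here follow the half-up
#' convention instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(1.005, 2)  # 1.01, where round() gives 1.00
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon absorbs binary representation error in values that are
  # exactly representable halves in decimal (e.g. 0.125)
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

is_valid_tripeptide <- function(x) {
  nchar(x) == 3L & !is.na(x) &
    vapply(strsplit(x, ""), function(ch) all(ch %in% AA_STANDARD), logical(1))
}

# Split a protein string into its residue characters.
residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# rbind a list of data frames, tolerating NULL entries and empty lists.
rbind_rows <- function(lst, empty) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(empty)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# sample one element of a vector, immune to the scalar-n expansion of sample().
sample_one <- function(x) x[sample.int(length(x), 1L)]
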