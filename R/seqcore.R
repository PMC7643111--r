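#' @importFrom Biostrings readAAStringSet
#' @importFrom stats runif rbinom setNames cor pnorm aggregate p.adjust
#' @importFrom utils read.csv write.csv write.table read.delim head
NULL

# The 20 proteinogenic amino acids, alphabetical by one-letter code.
# X is the only additional letter admitted in sequences; it marks
# non-standard or ambiguous residues and is excluded from all statistics.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Schechter & Berger subsite labels for a 12-residue cleavage window:
# P6..P1 amino-terminal (nonprime) of the scissile bond, P1'..P6' prime side.
SUBSITES <- c("P6", "P5", "P4", "P3", "P2", "P1",
              "P1'", "P2'", "P3'", "P4'", "P5'", "P6'")

# Monoisotopic and average residue (i.e. dehydrated) masses in Da.
RESIDUE_MASS_MONO <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)
RESIDUE_MASS_AVG <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528

# Typical amino-acid composition of a gram-negative bacterial proteome,
# used as the default residue distribution for synthetic proteomes.
AA_TYPICAL_FREQS <- c(
  A = 0.095, C = 0.012, D = 0.051, E = 0.058, F = 0.039, G = 0.074,
  H = 0.022, I = 0.060, K = 0.044, L = 0.106, M = 0.028, N = 0.039,
  P = 0.044, Q = 0.044, R = 0.055, S = 0.058, T = 0.054, V = 0.071,
  W = 0.015, Y = 0.031)
AA_TYPICAL_FREQS <- AA_TYPICAL_FREQS / sum(AA_TYPICAL_FREQS)

#' Create a protein record
#'
#' A `protein_record` holds a named amino-acid sequence together with an
#' optional signal-peptide annotation. Sequences are restricted to the 20
#' standard residues plus `X` (non-standard/ambiguous, excluded from all
#' statistics). All coordinates in the package are 1-based inclusive.
#'
#' @param id Accession string.
#' @param sequence Amino-acid sequence (coerced to upper case).
#' @param description Free-text description.
#' @param signal_peptide_length Number of amino-terminal residues removed to
#'   obtain the mature protein (default 0).
#' @param offset Coordinate offset already applied (set by [mature_form()];
#'   positions reported downstream are in the record's own coordinates).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "",
                           signal_peptide_length = 0L, offset = 0L) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence))
    stop("protein '", id, "': sequence must be non-empty")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_STANDARD, "X"))
  if (length(bad) > 0)
    stop("protein '", id, "': invalid residue letter(s): ",
         paste(unique(bad), collapse = ", "))
  signal_peptide_length <- as.integer(signal_peptide_length)
  if (signal_peptide_length < 0 || signal_peptide_length >= nchar(sequence))
    stop("protein '", id, "': signal_peptide_length must be in [0, length)")
  structure(list(id = as.character(id), description = as.character(description),
                 sequence = sequence,
                 signal_peptide_length = signal_peptide_length,
                 offset = as.integer(offset)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record '%s' (%d aa%s)\n", x$id, nchar(x$sequence),
              if (x$signal_peptide_length > 0)
                sprintf(", signal peptide %d aa", x$signal_peptide_length)
              else ""))
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased; the non-standard letters U, B, Z, J (and any
#' other non-alphabet character accepted by the FASTA reader) are mapped to
#' `X` with a single warning. Record order is preserved. Record ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A list of [protein_record()] objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error in ", path, ": expected '>' header at line ",
         first)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0)
    stop("FASTA format error in ", path, ": no records (line 1)")
  seqs <- toupper(as.character(aa))
  mapped <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs)
  n_mapped <- sum(nchar(gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", seqs)))
  if (n_mapped > 0)
    warning("read_fasta: mapped ", n_mapped,
            " non-standard residue(s) (e.g. U/B/Z/J) to X in ", path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  desc <- sub("^\\S+\\s*", "", headers)
  recs <- lapply(seq_along(ids), function(i)
    protein_record(ids[i], mapped[i], description = desc[i]))
  names(recs) <- ids
  recs
}

#' Write protein records to a FASTA file
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in proteins) {
    header <- if (nzchar(p$description)) paste(p$id, p$description) else p$id
    writeLines(paste0(">", header), con)
    s <- p$sequence
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Background amino-acid frequencies of a proteome
#'
#' Relative frequency of each of the 20 standard residues over a set of
#' proteins; `X` residues are excluded from both numerator and denominator.
#' This is the "natural abundance" reference used to normalise subsite
#' occurrences.
#'
#' @param proteins List of [protein_record()] objects.
#' @param proteome_id Identifier recorded with the frequencies.
#' @return A named numeric vector of length 20 summing to 1, class
#'   `background_frequencies`, with attribute `proteome_id`.
#' @export
background_frequencies <- function(proteins, proteome_id = "proteome") {
  if (length(proteins) == 0) stop("background_frequencies: empty proteome")
  all_seq <- paste(vapply(proteins, function(p) p$sequence, character(1)),
                   collapse = "")
  chars <- strsplit(all_seq, "")[[1]]
  chars <- chars[chars != "X"]
  if (length(chars) == 0)
    stop("background_frequencies: no countable (non-X) residues")
  counts <- table(factor(chars, levels = AA_STANDARD))
  freqs <- as.numeric(counts) / length(chars)
  structure(setNames(freqs, AA_STANDARD), class = "background_frequencies",
            proteome_id = proteome_id)
}

#' Export background frequencies as a two-column TSV
#'
#' @param freqs A [background_frequencies()] vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(freqs, path) {
  df <- data.frame(residue = names(freqs), frequency = as.numeric(freqs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Find motif occurrences in a sequence
#'
#' The motif expression consists of fixed amino-acid letters and the
#' wildcard `x` (any residue); dashes are ignored, so `"H-E-x-x-H"` and
#' `"HExxH"` are equivalent. Overlapping matches are reported.
#'
#' @param sequence Amino-acid string.
#' @param pattern Motif expression, e.g. `"HExxH"`.
#' @return Integer vector of 1-based match start positions, ascending
#'   (empty when the pattern is longer than the sequence or absent).
#' @export
find_motif <- function(sequence, pattern) {
  pattern <- gsub("-", "", pattern)
  if (!nzchar(pattern)) stop("find_motif: empty pattern")
  sequence <- toupper(sequence)
  if (nchar(pattern) > nchar(sequence)) return(integer(0))
  chars <- strsplit(toupper(pattern), "")[[1]]
  # lowercase x in the original pattern is the wildcard; uppercase letters
  # (including X) match literally
  orig <- strsplit(pattern, "")[[1]]
  rx <- paste(ifelse(orig %in% c("x", "."), ".", chars), collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m)
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water, on the monoisotopic or average
#' mass scale.
#'
#' @param sequence Amino-acid string without `X`.
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da.
#' @export
molecular_weight <- function(sequence, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("molecular_weight: empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  if (any(chars == "X"))
    stop("molecular_weight: sequence contains X (undefined composition)")
  tab <- if (mode == "monoisotopic") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  if (any(!chars %in% names(tab)))
    stop("molecular_weight: invalid residue(s)")
  sum(tab[chars]) + if (mode == "monoisotopic") WATER_MONO else WATER_AVG
}

#' Extract a subregion of a protein
#'
#' @param protein A [protein_record()].
#' @param start,end 1-based inclusive bounds.
#' @return A `protein_record` covering the region; its `offset` records the
#'   position of the region start in the parent's coordinates.
#' @export
extract_region <- function(protein, start, end) {
  n <- nchar(protein$sequence)
  if (start < 1 || end > n || start > end)
    stop("extract_region: bounds [", start, ", ", end,
         "] out of range for '", protein$id, "' (length ", n, ")")
  protein_record(protein$id, substr(protein$sequence, start, end),
                 description = protein$description,
                 offset = protein$offset + start - 1L)
}

#' Mature form of a protein
#'
#' Drops the annotated signal peptide and records the coordinate offset so
#' downstream positions are reported in mature coordinates.
#'
#' @param protein A [protein_record()].
#' @return A `protein_record` for the mature sequence
#'   (`signal_peptide_length` 0, `offset` set to the removed length).
#' @export
mature_form <- function(protein) {
  k <- protein$signal_peptide_length
  if (k == 0) return(protein)
  protein_record(protein$id,
                 substr(protein$sequence, k + 1L, nchar(protein$sequence)),
                 description = protein$description,
                 offset = protein$offset + k)
}

#' Count residues from a set
#'
#' @param x A `protein_record` or amino-acid string.
#' @param residues Non-empty character vector of residue letters.
#' @return Number of positions whose letter is in `residues`.
#' @export
aa_count <- function(x, residues) {
  if (inherits(x, "protein_record")) x <- x$sequence
  if (length(residues) == 0) stop("aa_count: empty residue set")
  sum(strsplit(toupper(x), "")[[1]] %in% toupper(residues))
}

# Slice the 12-residue P6-P6' window around the scissile bond after
# position p1 (1-based), X-padding beyond the protein ends.
slice_window <- function(sequence, p1) {
  n <- nchar(sequence)
  pos <- (p1 - 5L):(p1 + 6L)
  chars <- ifelse(pos < 1 | pos > n, "X",
                  substring(sequence, pmax(pos, 1L), pmax(pos, 1L)))
  paste(chars, collapse = "")
}
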