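#' Define a digestion enzyme
#'
#' An enzyme is described by the residues after which it cleaves (the P1
#' set) and an optional set of residues that suppress cleavage when found
#' immediately C-terminal to the bond (the classic proline block of
#' trypsin).
#'
#' @param name Enzyme name.
#' @param p1_residues Residues after which the enzyme cleaves.
#' @param blocked_p1prime_residues Residues that block cleavage when in P1'.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, p1_residues, blocked_p1prime_residues = character()) {
  p1_residues <- toupper(p1_residues)
  blocked_p1prime_residues <- toupper(blocked_p1prime_residues)
  if (length(p1_residues) == 0) stop("enzyme_spec: p1_residues must be non-empty")
  if ("X" %in% c(p1_residues, blocked_p1prime_residues))
    stop("enzyme_spec: X is not a valid specificity residue")
  if (!all(c(p1_residues, blocked_p1prime_residues) %in% AA_STANDARD))
    stop("enzyme_spec: residues must be standard amino-acid letters")
  structure(list(name = name, p1_residues = p1_residues,
                 blocked_p1prime_residues = blocked_p1prime_residues),
            class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @param block_proline Suppress cleavage before proline (default TRUE).
#' @export
trypsin <- function(block_proline = TRUE) {
  enzyme_spec("trypsin", c("K", "R"),
              if (block_proline) "P" else character())
}

#' @rdname enzyme_spec
#' @export
gluc <- function() enzyme_spec("GluC", c("D", "E"))

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("enzyme_spec '%s': cleaves after [%s]%s\n", x$name,
              paste(x$p1_residues, collapse = ""),
              if (length(x$blocked_p1prime_residues))
                sprintf(" except before [%s]",
                        paste(x$blocked_p1prime_residues, collapse = ""))
              else ""))
  invisible(x)
}

# 1-based positions p such that the enzyme cleaves between p and p+1.
cleavage_positions <- function(sequence, enzyme) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  p <- which(chars[-n] %in% enzyme$p1_residues)
  if (length(enzyme$blocked_p1prime_residues) > 0)
    p <- p[!chars[p + 1L] %in% enzyme$blocked_p1prime_residues]
  p
}

#' In-silico digestion of a protein
#'
#' Cleaves after every P1 residue of the enzyme unless the following residue
#' is blocked, enumerating products with 0 to `max_missed` missed cleavage
#' sites. With `max_missed = 0` and no length filter the products partition
#' the protein exactly. The length filter is applied last.
#'
#' @param protein A [protein_record()] (or plain sequence string).
#' @param enzyme An [enzyme_spec()].
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param min_length,max_length Peptide length bounds applied after
#'   enumeration.
#' @return A data.frame with columns `protein`, `peptide`, `start`, `end`,
#'   `missed` (1-based inclusive coordinates).
#' @export
digest_protein <- function(protein, enzyme, max_missed = 0L,
                           min_length = 1L, max_length = Inf) {
  if (!inherits(protein, "protein_record"))
    protein <- protein_record("protein", protein)
  seqs <- protein$sequence
  cuts <- cleavage_positions(seqs, enzyme)
  bounds <- c(0L, cuts, nchar(seqs))
  nf <- length(bounds) - 1L  # number of fully specific fragments
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    if (nf - m < 1) break
    i <- seq_len(nf - m)
    out[[m + 1L]] <- data.frame(start = bounds[i] + 1L,
                                end = bounds[i + m + 1L],
                                missed = m)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  len <- df$end - df$start + 1L
  df <- df[len >= min_length & len <= max_length, , drop = FALSE]
  data.frame(protein = rep(protein$id, nrow(df)),
             peptide = substring(seqs, df$start, df$end),
             start = df$start, end = df$end, missed = df$missed,
             stringsAsFactors = FALSE, row.names = NULL)
}
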