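#' Experiment design for channel-labeled degradomics
#'
#' Describes how to interpret a pair of PSM tables: which enzyme generated
#' the peptide library, which dimethyl label marks which channel, the
#' per-PSM confidence threshold (default 0.99, emulating a 1% false
#' discovery rate cut-off), and whether a prime-side product also observed
#' in the control channel should be demoted to ambiguous.
#'
#' @param library_enzyme An [enzyme_spec()].
#' @param control_label,treated_label Dimethyl label names
#'   (`"light"`/`"heavy"`), must differ.
#' @param confidence_threshold Minimum PSM confidence retained.
#' @param require_treated_only Demote prime-side products whose sequence is
#'   also seen in the control channel (default TRUE).
#' @param collapse_il Treat I and L as indistinguishable during mapping
#'   (default FALSE).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(library_enzyme = trypsin(),
                              control_label = "light",
                              treated_label = "heavy",
                              confidence_threshold = 0.99,
                              require_treated_only = TRUE,
                              collapse_il = FALSE) {
  if (identical(control_label, treated_label))
    stop("experiment_design: control and treated labels must differ")
  if (confidence_threshold < 0 || confidence_threshold > 1)
    stop("experiment_design: confidence_threshold must be in [0, 1]")
  structure(list(library_enzyme = library_enzyme,
                 control_label = control_label,
                 treated_label = treated_label,
                 confidence_threshold = confidence_threshold,
                 require_treated_only = require_treated_only,
                 collapse_il = collapse_il),
            class = "experiment_design")
}

# Parse one "name@position(delta)" modification entry list.
parse_modifications <- function(modstring) {
  if (is.na(modstring) || !nzchar(modstring)) {
    return(data.frame(name = character(), position = character(),
                      delta = numeric()))
  }
  entries <- strsplit(modstring, ";", fixed = TRUE)[[1]]
  m <- regmatches(entries,
                  regexec("^\\s*([^@]+)@(nterm|[0-9]+)\\((-?[0-9.]+)\\)\\s*$",
                          entries))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad))
    stop("unparsable modification entry: ",
         paste(entries[bad], collapse = "; "))
  data.frame(name = vapply(m, `[`, character(1), 2),
             position = vapply(m, `[`, character(1), 3),
             delta = as.numeric(vapply(m, `[`, character(1), 4)))
}

#' Parse a PSM table
#'
#' Reads a search-engine style CSV export with mandatory columns `peptide`,
#' `proteins` (semicolon-separated accessions), `modifications`
#' (semicolon-separated `name@position(delta)` entries, position `nterm` or
#' a 1-based residue index), `confidence` (0-1) and `sample`. Rows below
#' the confidence threshold are dropped and counted; unparsable
#' modification strings are collected as row-level errors.
#'
#' @param path CSV path.
#' @param confidence_threshold Minimum confidence retained (default 0.99).
#' @return Data.frame of retained records with a list-column `mods`;
#'   attributes `n_excluded_confidence` and `row_errors`.
#' @export
parse_psm_table <- function(path, confidence_threshold = 0.99) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  required <- c("peptide", "proteins", "modifications", "confidence", "sample")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("PSM table ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df$confidence <- as.numeric(df$confidence)
  if (any(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1))
    stop("PSM table ", path, ": confidence values must be in [0, 1]")
  if (any(!nzchar(df$peptide)))
    stop("PSM table ", path, ": empty peptide sequence")
  n_before <- nrow(df)
  df <- df[df$confidence >= confidence_threshold, , drop = FALSE]
  n_excluded <- n_before - nrow(df)
  if (n_excluded > 0)
    message("parse_psm_table: excluded ", n_excluded,
            " row(s) below confidence ", confidence_threshold)
  mods <- vector("list", nrow(df))
  row_errors <- character()
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    parsed <- tryCatch(parse_modifications(df$modifications[i]),
                       error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      row_errors <- c(row_errors, sprintf("row %d: %s", i, parsed))
      keep[i] <- FALSE
    } else mods[[i]] <- parsed
  }
  df <- df[keep, , drop = FALSE]
  df$mods <- mods[keep]
  rownames(df) <- NULL
  attr(df, "n_excluded_confidence") <- n_excluded
  attr(df, "row_errors") <- row_errors
  df
}

#' Build a substring index over a proteome
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param collapse_il Fold I and L together for matching.
#' @return An opaque index object for [map_peptide()].
#' @export
proteome_index <- function(proteome, collapse_il = FALSE) {
  seqs <- vapply(proteome, function(p) p$sequence, character(1))
  lens <- nchar(seqs)
  concat <- paste(seqs, collapse = "#")
  if (collapse_il) concat <- gsub("I", "L", concat, fixed = TRUE)
  structure(list(concat = concat, ids = names(proteome), lengths = lens,
                 offsets = cumsum(c(0L, head(lens + 1L, -1L))),
                 proteome = proteome, collapse_il = collapse_il),
            class = "proteome_index")
}

#' Map a peptide sequence onto the proteome
#'
#' Reports every exact substring occurrence with 1-based inclusive
#' coordinates. I and L are distinct unless the index was built with
#' `collapse_il = TRUE`.
#'
#' @param sequence Peptide sequence.
#' @param index A [proteome_index()].
#' @return Data.frame with `protein`, `start`, `end` (0 rows if absent).
#' @export
map_peptide <- function(sequence, index) {
  query <- toupper(sequence)
  if (index$collapse_il) query <- gsub("I", "L", query, fixed = TRUE)
  m <- gregexpr(query, index$concat, fixed = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(protein = character(), start = integer(),
                      end = integer()))
  gpos <- as.integer(m)
  k <- findInterval(gpos, index$offsets + 1L)
  start <- gpos - index$offsets[k]
  data.frame(protein = index$ids[k], start = start,
             end = start + nchar(query) - 1L, row.names = NULL)
}

# Channel of a PSM from its amino-terminal label.
detect_channel <- function(mods, design) {
  nterm <- mods[mods$position == "nterm", , drop = FALSE]
  if (nrow(nterm) == 0) return(list(channel = "unknown", reason = "no_nterm_label"))
  name <- tolower(nterm$name[1])
  if (grepl("acetyl|pyro", name))
    return(list(channel = "unknown", reason = "blocked_nterm"))
  if (grepl(design$treated_label, name))
    return(list(channel = "treated", reason = ""))
  if (grepl(design$control_label, name))
    return(list(channel = "control", reason = ""))
  list(channel = "unknown", reason = "unrecognised_nterm_label")
}

#' Classify labeled peptides by channel and origin
#'
#' The channel comes from the amino-terminal dimethyl label (light =
#' control, heavy = treated; blocked or missing termini give `unknown`).
#' Origin rules, applied after mapping each peptide to the proteome:
#' a treated-channel peptide whose preceding (P1-context) residue is not a
#' library-enzyme P1 residue is a `prime_side_product`; a peptide whose
#' context matches the library enzyme (or sits at a protein amino terminus)
#' is a `library_peptide`; blocked termini, unmappable peptides and
#' conflicting multi-mappings are `ambiguous` with a reason code. When the
#' design's `require_treated_only` flag is set, a prime-side product whose
#' sequence also occurs in the control channel is demoted to ambiguous.
#'
#' @param records PSM data.frame from [parse_psm_table()] (both channels
#'   may be concatenated, or supplied separately and rbound by the caller).
#' @param design An [experiment_design()].
#' @param index A [proteome_index()].
#' @return The records with added columns `channel`, `origin`, `reason`.
#' @export
classify_peptides <- function(records, design, index) {
  n <- nrow(records)
  channel <- character(n); origin <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    ch <- detect_channel(records$mods[[i]], design)
    channel[i] <- ch$channel
    if (ch$channel == "unknown") {
      origin[i] <- "ambiguous"; reason[i] <- ch$reason
      next
    }
    hits <- map_peptide(records$peptide[i], index)
    if (nrow(hits) == 0) {
      origin[i] <- "ambiguous"; reason[i] <- "unmappable"
      next
    }
    ctx <- peptide_context(hits, index, design$library_enzyme$p1_residues)
    if (all(ctx$library_consistent)) {
      origin[i] <- "library_peptide"; reason[i] <- ""
    } else if (any(ctx$library_consistent)) {
      origin[i] <- "ambiguous"; reason[i] <- "conflicting_context"
    } else if (channel[i] == "treated") {
      origin[i] <- "prime_side_product"; reason[i] <- ""
    } else {
      # semi-specific terminus in the control channel: background, not a
      # cleavage product of the protease under study
      origin[i] <- "ambiguous"; reason[i] <- "semi_specific_in_control"
    }
  }
  records$channel <- channel
  records$origin <- origin
  records$reason <- reason
  if (design$require_treated_only) {
    control_seqs <- unique(records$peptide[records$channel == "control"])
    demote <- records$origin == "prime_side_product" &
      records$peptide %in% control_seqs
    records$origin[demote] <- "ambiguous"
    records$reason[demote] <- "observed_in_control"
  }
  records
}

# For every mapping, is the peptide's amino-terminal context consistent
# with the library enzyme (preceding residue in the enzyme's P1 set, or a
# protein N-terminus)?
peptide_context <- function(hits, index, enzyme_p1) {
  prev <- vapply(seq_len(nrow(hits)), function(j) {
    if (hits$start[j] == 1L) return(">")
    substr(index$proteome[[hits$protein[j]]]$sequence,
           hits$start[j] - 1L, hits$start[j] - 1L)
  }, character(1))
  list(prev = prev, library_consistent = prev == ">" | prev %in% enzyme_p1)
}

#' Reconstruct unique P6-P6' cleavage sites from classified peptides
#'
#' Each prime-side product's mapping places the scissile bond immediately
#' before the peptide (P1 = start - 1); the complete 12-residue window is
#' read from the proteome with X padding at protein ends. Peptides whose
#' multiple mappings disagree on the window are dropped as ambiguous;
#' candidate sites whose P1 residue belongs to the library enzyme are
#' excluded (attribution `library_enzyme`); protein amino termini never
#' yield sites. Surviving sites are deduplicated on the window string.
#'
#' @param classified Output of [classify_peptides()].
#' @param index A [proteome_index()].
#' @param design An [experiment_design()].
#' @param experiment Experiment tag recorded on each site.
#' @return List with `sites` (data.frame: `window`, `protein`,
#'   `p1_position`, `attribution`, `n_supporting_peptides`, `experiment`)
#'   and `census` (named list of bookkeeping counts, including unique
#'   window- and protein-position-level site counts).
#' @export
reconstruct_sites <- function(classified, index, design,
                              experiment = "pics") {
  prime <- classified[classified$origin == "prime_side_product", ,
                      drop = FALSE]
  census <- list(
    input_peptides = nrow(classified),
    prime_side_products = nrow(prime),
    library_peptides = sum(classified$origin == "library_peptide"),
    ambiguous = sum(classified$origin == "ambiguous"),
    window_conflicts = 0L, library_attributed = 0L, terminus_only = 0L)
  rows <- list()
  for (i in seq_len(nrow(prime))) {
    hits <- map_peptide(prime$peptide[i], index)
    hits <- hits[hits$start > 1L, , drop = FALSE]
    if (nrow(hits) == 0) { census$terminus_only <- census$terminus_only + 1L; next }
    wins <- vapply(seq_len(nrow(hits)), function(j)
      slice_window(index$proteome[[hits$protein[j]]]$sequence,
                   hits$start[j] - 1L), character(1))
    if (length(unique(wins)) > 1) {
      census$window_conflicts <- census$window_conflicts + 1L
      next
    }
    p1_res <- substr(wins[1], 6, 6)
    if (p1_res %in% design$library_enzyme$p1_residues) {
      census$library_attributed <- census$library_attributed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      window = wins[1], protein = hits$protein[1],
      p1_position = hits$start[1] - 1L,
      attribution = "target_protease")
  }
  if (length(rows) == 0) {
    sites <- data.frame(window = character(), protein = character(),
                        p1_position = integer(), attribution = character(),
                        n_supporting_peptides = integer(),
                        experiment = character())
    census$unique_windows <- 0L
    census$unique_protein_positions <- 0L
    return(list(sites = sites, census = census))
  }
  all_sites <- do.call(rbind, rows)
  agg <- aggregate(list(n_supporting_peptides = all_sites$window),
                   by = list(window = all_sites$window), FUN = length)
  first <- all_sites[!duplicated(all_sites$window), , drop = FALSE]
  sites <- merge(first, agg, by = "window", sort = TRUE)
  sites$experiment <- experiment
  sites <- sites[order(sites$protein, sites$p1_position), , drop = FALSE]
  rownames(sites) <- NULL
  census$unique_windows <- nrow(sites)
  census$unique_protein_positions <-
    nrow(unique(all_sites[, c("protein", "p1_position")]))
  list(sites = sites, census = census)
}

#' Write reconstructed sites as TSV
#'
#' @param sites Site data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site TSV written by [write_sites()]
#'
#' @param path TSV path.
#' @return Site data.frame.
#' @export
read_sites <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
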