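#' Position-weight specificity model of a protease
#'
#' The ground-truth model driving the simulator: one probability-weight
#' vector over the 20 standard residues per subsite (P6..P6'), plus an
#' overall cleavage propensity. Uniform weights at a subsite encode "no
#' preference". The per-bond cleavage probability is
#' `propensity * prod_s(20 * w_s(aa_s))`, capped at 1, so a fully uniform
#' model cleaves every bond with probability `propensity` and concentrated
#' weights raise or lower the odds in proportion to the weight product;
#' X-padded context beyond a protein end contributes a neutral factor.
#'
#' @param weights A 20 x 12 numeric matrix (rows = residues in
#'   [AA_STANDARD] order, columns = subsites P6..P6'); each column must sum
#'   to 1. `NULL` gives uniform weights everywhere.
#' @param propensity Overall cleavage propensity in \[0, 1\] (0 disables
#'   cleavage entirely).
#' @return An object of class `specificity_model`.
#' @export
specificity_model <- function(weights = NULL, propensity = 0.1) {
  if (is.null(weights))
    weights <- matrix(1 / 20, nrow = 20, ncol = 12,
                      dimnames = list(AA_STANDARD, SUBSITES))
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(20, 12)))
    stop("specificity_model: weights must be 20 x 12")
  dimnames(weights) <- list(AA_STANDARD, SUBSITES)
  if (any(weights < 0)) stop("specificity_model: negative weights")
  csums <- colSums(weights)
  if (any(abs(csums - 1) > 1e-9))
    stop("specificity_model: each subsite's weights must sum to 1")
  if (propensity < 0 || propensity > 1)
    stop("specificity_model: propensity must be in [0, 1]")
  structure(list(weights = weights, propensity = propensity),
            class = "specificity_model")
}

#' Set the residue preference of one subsite
#'
#' Convenience editor: named entries fix the weights of specific residues,
#' and the remaining probability mass is spread uniformly over the other
#' residues.
#'
#' @param model A [specificity_model()].
#' @param subsite Subsite label, e.g. `"P1'"`.
#' @param prefs Named numeric vector of residue weights (sum must be <= 1).
#' @return The modified model.
#' @export
set_subsite_preference <- function(model, subsite, prefs) {
  if (!subsite %in% SUBSITES) stop("unknown subsite: ", subsite)
  if (any(!names(prefs) %in% AA_STANDARD)) stop("unknown residue in prefs")
  rest <- setdiff(AA_STANDARD, names(prefs))
  leftover <- 1 - sum(prefs)
  if (leftover < -1e-12) stop("preferences sum to more than 1")
  w <- rep(leftover / length(rest), 20)
  names(w) <- rep(NA, 20)
  w <- setNames(rep(leftover / length(rest), 20), AA_STANDARD)
  w[names(prefs)] <- prefs
  model$weights[, subsite] <- w / sum(w)
  model
}

#' Simulation configuration
#'
#' Bundles the experimental design of a simulated peptide-library
#' degradomics run: library enzyme, digestion parameters, detectability
#' bounds, identification noise, and the dimethyl channel plan (control =
#' light, protease-treated = heavy).
#'
#' @param library_enzyme An [enzyme_spec()] (default [trypsin()]).
#' @param max_missed Missed cleavages in the library digest (default 0).
#' @param min_length Minimum detectable peptide length (>= 4: shorter
#'   peptides are below the practical MS detection range).
#' @param max_length Maximum detectable peptide length.
#' @param identification_rate Probability that a peptide present in a
#'   channel is identified (default 1).
#' @param decoy_rate Expected fraction of shuffled-sequence contaminant rows
#'   injected per channel (default 0).
#' @param seed Random seed governing all stochastic steps.
#' @param channels Channel plan mapping `control`/`treated` to label names.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(library_enzyme = trypsin(), max_missed = 0L,
                              min_length = 4L, max_length = 45L,
                              identification_rate = 1, decoy_rate = 0,
                              seed = 1L,
                              channels = c(control = "light", treated = "heavy")) {
  if (min_length < 4)
    stop("simulation_config: min_length must be >= 4 (undetectable peptides)")
  if (identification_rate < 0 || identification_rate > 1)
    stop("simulation_config: identification_rate must be in [0, 1]")
  if (decoy_rate < 0 || decoy_rate > 1)
    stop("simulation_config: decoy_rate must be in [0, 1]")
  if (!all(c("control", "treated") %in% names(channels)))
    stop("simulation_config: channels must name 'control' and 'treated'")
  structure(list(library_enzyme = library_enzyme,
                 max_missed = as.integer(max_missed),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 identification_rate = identification_rate,
                 decoy_rate = decoy_rate, seed = as.integer(seed),
                 channels = channels),
            class = "simulation_config")
}

#' Generate a random synthetic proteome
#'
#' Protein sequences drawn i.i.d. from a residue distribution; used to
#' emulate the biological amino-acid diversity of a whole-proteome extract.
#'
#' @param n_proteins Number of proteins.
#' @param min_length,max_length Uniform protein-length bounds.
#' @param frequencies Residue distribution (named, 20 entries; default
#'   [AA_TYPICAL_FREQS], a typical bacterial proteome composition).
#' @param seed Random seed.
#' @param prefix Accession prefix.
#' @return Named list of [protein_record()] objects.
#' @export
random_proteome <- function(n_proteins, min_length = 200L, max_length = 400L,
                            frequencies = AA_TYPICAL_FREQS, seed = 1L,
                            prefix = "SYN") {
  stopifnot(n_proteins >= 1, min_length >= 12)
  frequencies <- frequencies[AA_STANDARD]
  frequencies <- frequencies / sum(frequencies)
  set.seed(seed)
  lens <- sample(min_length:max_length, n_proteins, replace = TRUE)
  recs <- lapply(seq_len(n_proteins), function(i) {
    s <- paste(sample(AA_STANDARD, lens[i], replace = TRUE,
                      prob = frequencies), collapse = "")
    protein_record(sprintf("%s%04d", prefix, i), s,
                   description = "synthetic protein")
  })
  names(recs) <- vapply(recs, function(p) p$id, character(1))
  recs
}

#' Build a proteome-derived peptide library
#'
#' Union of the in-silico digests of every protein in the proteome with the
#' configured library enzyme. Deterministic given the configuration.
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param config A [simulation_config()].
#' @return Data.frame of library peptides with `protein`, `peptide`,
#'   `start`, `end`, `missed`.
#' @export
build_library <- function(proteome, config) {
  if (length(proteome) == 0) stop("build_library: empty proteome")
  out <- lapply(proteome, digest_protein, enzyme = config$library_enzyme,
                max_missed = config$max_missed,
                min_length = config$min_length,
                max_length = config$max_length)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Per-position cleavage probability for every internal bond of a protein:
# prob[p] applies to the bond between residues p and p+1.
bond_probabilities <- function(sequence, model) {
  n <- nchar(sequence)
  if (n < 2 || model$propensity == 0) return(rep(0, max(n - 1L, 0L)))
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_STANDARD)            # NA for X
  factors <- 20 * model$weights               # neutral value 1 at uniform
  score <- rep(1, n - 1L)
  p <- seq_len(n - 1L)
  for (s in seq_len(12L)) {
    off <- s - 6L                             # P6 -> -5 ... P6' -> +6
    pos <- p + off
    ok <- pos >= 1L & pos <= n & !is.na(idx[pmax(pmin(pos, n), 1L)])
    f <- rep(1, n - 1L)
    f[ok] <- factors[idx[pos[ok]], s]
    score <- score * f
  }
  pmin(1, model$propensity * score)
}

#' Simulate protease cleavage of a peptide library
#'
#' For each internal bond of each library peptide the cleavage probability
#' is computed from the full protein context of its P6-P6' window (see
#' [specificity_model()]). Scanning amino- to carboxy-terminal, the first
#' accepted bond cuts the peptide into a nonprime and a prime fragment; at
#' most one cut per peptide. Uncut peptides pass through to the treated
#' channel unchanged. Every cut is recorded in the ground truth.
#'
#' @param library Library data.frame from [build_library()].
#' @param proteome The proteome the library was digested from.
#' @param model A [specificity_model()].
#' @param config A [simulation_config()] (detectability bounds and library
#'   enzyme are needed to annotate recoverability).
#' @return List with `treated` (data.frame of treated-channel peptides with
#'   `origin` in library_peptide/prime_side_product/nonprime_product) and
#'   `ground_truth` (data.frame of simulated cleavage sites: `protein`,
#'   `p1`, `window`, `prime_length`, `detectable`, `recoverable`).
#' @export
simulate_protease_cleavage <- function(library, proteome, model, config) {
  set.seed(config$seed)
  probs <- lapply(proteome, function(p) bond_probabilities(p$sequence, model))
  n <- nrow(library)
  cutpos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- library$start[i]; e <- library$end[i]
    if (e > s) {
      bonds <- s:(e - 1L)
      u <- runif(length(bonds))
      hit <- which(u < probs[[library$protein[i]]][bonds])
      if (length(hit) > 0) cutpos[i] <- bonds[hit[1]]
    }
  }
  prot_seq <- vapply(proteome, `[[`, character(1), "sequence")
  uncut <- which(is.na(cutpos))
  cut <- which(!is.na(cutpos))
  seqs_cut <- prot_seq[library$protein[cut]]
  treated <- rbind(
    data.frame(protein = library$protein[uncut],
               peptide = library$peptide[uncut],
               start = library$start[uncut], end = library$end[uncut],
               origin = rep("library_peptide", length(uncut))),
    data.frame(protein = library$protein[cut],
               peptide = substr(seqs_cut, library$start[cut], cutpos[cut]),
               start = library$start[cut], end = cutpos[cut],
               origin = rep("nonprime_product", length(cut))),
    data.frame(protein = library$protein[cut],
               peptide = substr(seqs_cut, cutpos[cut] + 1L, library$end[cut]),
               start = cutpos[cut] + 1L, end = library$end[cut],
               origin = rep("prime_side_product", length(cut))))
  rownames(treated) <- NULL
  if (length(cut) == 0) {
    gt <- data.frame(protein = character(), p1 = integer(),
                     peptide_start = integer(), peptide_end = integer(),
                     window = character(), prime_length = integer(),
                     detectable = logical(), recoverable = logical())
  } else {
    gt <- data.frame(protein = library$protein[cut], p1 = cutpos[cut],
                     peptide_start = library$start[cut],
                     peptide_end = library$end[cut])
    gt$window <- vapply(seq_len(nrow(gt)), function(i)
      slice_window(prot_seq[[gt$protein[i]]], gt$p1[i]), character(1))
    gt$prime_length <- gt$peptide_end - gt$p1
    gt$detectable <- gt$prime_length >= config$min_length &
      gt$prime_length <= config$max_length
    gt$recoverable <- annotate_recoverable(gt, proteome, config,
                                           library$peptide)
  }
  list(treated = treated, ground_truth = gt)
}

# A simulated site is recoverable from the emitted tables when its prime
# fragment is detectable, its P1 residue is not attributable to the library
# enzyme, the fragment sequence does not collide with a control-channel
# library peptide (which would demote it under the treated-only rule), and
# every proteome occurrence of the fragment yields the identical window
# (otherwise the pipeline must drop it as ambiguous).
annotate_recoverable <- function(gt, proteome, config, library_peptides) {
  concat <- paste(vapply(proteome, function(p) p$sequence, character(1)),
                  collapse = "#")
  ids <- names(proteome)
  lens <- vapply(proteome, function(p) nchar(p$sequence), integer(1))
  offsets <- cumsum(c(0L, head(lens + 1L, -1L)))
  control_seqs <- unique(library_peptides)
  vapply(seq_len(nrow(gt)), function(i) {
    if (!gt$detectable[i]) return(FALSE)
    pseq <- proteome[[gt$protein[i]]]$sequence
    p1_res <- substr(pseq, gt$p1[i], gt$p1[i])
    if (p1_res %in% config$library_enzyme$p1_residues) return(FALSE)
    frag <- substr(pseq, gt$p1[i] + 1L, gt$peptide_end[i])
    if (frag %in% control_seqs) return(FALSE)
    m <- gregexpr(frag, concat, fixed = TRUE)[[1]]
    if (m[1] == -1) return(FALSE)
    wins <- vapply(as.integer(m), function(gpos) {
      k <- findInterval(gpos, offsets + 1L)
      local_start <- gpos - offsets[k]
      if (local_start == 1L) return(NA_character_)  # protein N-terminus
      slice_window(proteome[[ids[k]]]$sequence, local_start - 1L)
    }, character(1))
    wins <- wins[!is.na(wins)]
    length(wins) > 0 && length(unique(wins)) == 1
  }, logical(1))
}

# Modification-string helpers ------------------------------------------------

dimethyl_mods <- function(peptide, label) {
  delta <- if (label == "light") "28.05" else "34.06"
  name <- paste0("dimethyl-", label)
  mods <- sprintf("%s@nterm(%s)", name, delta)
  kpos <- which(strsplit(peptide, "")[[1]] == "K")
  if (length(kpos) > 0)
    mods <- c(mods, sprintf("%s@%d(%s)", name, kpos, delta))
  paste(mods, collapse = ";")
}

#' Emit peptide-spectrum-match tables for both channels
#'
#' Control rows are the library peptides carrying light dimethyl labels on
#' the amino terminus and lysines (+28.05 Da nominal); treated rows carry
#' heavy labels (+34.06 Da) and consist of uncut library peptides plus the
#' cleavage fragments that fall within the detectable length bounds.
#' Coordinates are deliberately not emitted: the analysis pipeline must
#' re-map every peptide to the proteome. The identification rate subsamples
#' rows; the decoy rate injects shuffled-sequence contaminant rows that are
#' flagged only in the returned decoy registry.
#'
#' @param library Library data.frame.
#' @param treated Treated-channel data.frame from
#'   [simulate_protease_cleavage()].
#' @param config A [simulation_config()].
#' @return List with `control` and `treated` PSM data.frames (columns
#'   `peptide`, `proteins`, `modifications`, `confidence`, `sample`) and
#'   `decoys`, a per-channel registry of injected contaminant rows.
#' @export
emit_psm_tables <- function(library, treated, config) {
  set.seed(config$seed + 1L)
  make_channel <- function(df, channel) {
    label <- config$channels[[channel]]
    len <- nchar(df$peptide)
    df <- df[len >= config$min_length & len <= config$max_length, ,
             drop = FALSE]
    keep <- runif(nrow(df)) < config$identification_rate
    df <- df[keep, , drop = FALSE]
    psm <- data.frame(
      peptide = df$peptide,
      proteins = df$protein,
      modifications = vapply(df$peptide, dimethyl_mods, character(1),
                             label = label, USE.NAMES = FALSE),
      confidence = rep(1, nrow(df)),
      sample = rep(channel, nrow(df)))
    n_decoy <- rbinom(1, nrow(psm), config$decoy_rate)
    decoys <- NULL
    if (n_decoy > 0) {
      src <- sample(seq_len(nrow(psm)), n_decoy, replace = TRUE)
      shuf <- vapply(psm$peptide[src], function(s)
        paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1),
        USE.NAMES = FALSE)
      decoys <- data.frame(
        peptide = shuf,
        proteins = psm$proteins[src],
        modifications = vapply(shuf, dimethyl_mods, character(1),
                               label = label, USE.NAMES = FALSE),
        confidence = rep(1, n_decoy),
        sample = rep(channel, n_decoy))
      psm <- rbind(psm, decoys)
    }
    rownames(psm) <- NULL
    list(psm = psm, decoys = decoys)
  }
  ctrl <- make_channel(library, "control")
  trt <- make_channel(treated, "treated")
  list(control = ctrl$psm, treated = trt$psm,
       decoys = list(control = ctrl$decoys, treated = trt$decoys))
}

#' Run a complete simulated PICS experiment
#'
#' Orchestrates [build_library()], [simulate_protease_cleavage()] and
#' [emit_psm_tables()] under a single seed so that identical configurations
#' produce byte-identical outputs.
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param model A [specificity_model()].
#' @param config A [simulation_config()].
#' @return List with `library`, `treated`, `ground_truth`, `psm` (control /
#'   treated tables plus decoy registry) and the `config` used.
#' @export
simulate_experiment <- function(proteome, model, config = simulation_config()) {
  library <- build_library(proteome, config)
  sim <- simulate_protease_cleavage(library, proteome, model, config)
  psm <- emit_psm_tables(library, sim$treated, config)
  list(library = library, treated = sim$treated,
       ground_truth = sim$ground_truth, psm = psm, config = config)
}

#' Write a PSM table as CSV
#'
#' @param psm PSM data.frame (the dialect of [parse_psm_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  write.csv(psm, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param ground_truth Ground-truth data.frame from
#'   [simulate_protease_cleavage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate digestion of an intact protein substrate
#'
#' Unlike library peptides, an intact substrate accumulates many cleavage
#' events: every internal bond is cut independently with the model's
#' probability, the accepted cuts partition the protein into products, and
#' in `sequential_trypsin` mode each product is subsequently digested with
#' the orthogonal enzyme to shorten it for detection. Ground truth records
#' every target cut with its window and whether it remains recoverable
#' from the emitted (length-filtered) products: at least one flanking
#' product must be detectable, and in sequential mode the P1 residue must
#' not be attributable to the orthogonal enzyme.
#'
#' @param substrate A [protein_record()] (mature form).
#' @param model A [specificity_model()].
#' @param config A [simulation_config()] (length bounds, seed).
#' @param mode `"single_protease"` or `"sequential_trypsin"`.
#' @param orthogonal Orthogonal enzyme for sequential mode.
#' @return List with `products` (data.frame `peptide`, `start`, `end`) of
#'   detectable products and `ground_truth` (data.frame `protein`, `p1`,
#'   `window`, `recoverable`).
#' @export
simulate_substrate_digest <- function(substrate, model, config,
                                      mode = c("single_protease",
                                               "sequential_trypsin"),
                                      orthogonal = trypsin()) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  seqs <- substrate$sequence
  n <- nchar(seqs)
  pb <- bond_probabilities(seqs, model)
  cuts <- which(runif(length(pb)) < pb)
  bounds <- sort(unique(c(0L, cuts, n)))
  frags <- data.frame(start = head(bounds, -1) + 1L, end = bounds[-1])
  if (mode == "sequential_trypsin") {
    tcuts <- cleavage_positions(seqs, orthogonal)
    pieces <- lapply(seq_len(nrow(frags)), function(i) {
      inner <- tcuts[tcuts >= frags$start[i] & tcuts < frags$end[i]]
      b <- c(frags$start[i] - 1L, inner, frags$end[i])
      data.frame(start = head(b, -1) + 1L, end = b[-1])
    })
    products <- do.call(rbind, pieces)
  } else {
    products <- frags
  }
  len <- products$end - products$start + 1L
  detectable <- len >= config$min_length & len <= config$max_length
  emitted <- products[detectable, , drop = FALSE]
  emitted$peptide <- substring(seqs, emitted$start, emitted$end)
  gt <- data.frame(protein = rep(substrate$id, length(cuts)), p1 = cuts)
  if (length(cuts) > 0) {
    gt$window <- vapply(cuts, function(p1) slice_window(seqs, p1),
                        character(1))
    # a cut is recoverable when a detectable product ends at it (C-terminal
    # evidence) or starts just after it (N-terminal evidence)
    gt$recoverable <- vapply(cuts, function(p1)
      any(emitted$end == p1) || any(emitted$start == p1 + 1L), logical(1))
    if (mode == "sequential_trypsin") {
      p1_res <- substring(seqs, cuts, cuts)
      gt$recoverable <- gt$recoverable &
        !p1_res %in% orthogonal$p1_residues
    }
  } else {
    gt$window <- character(0)
    gt$recoverable <- logical(0)
  }
  list(products = emitted[, c("peptide", "start", "end")], ground_truth = gt)
}
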