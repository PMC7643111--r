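#' Define a protein-substrate cleavage experiment
#'
#' A substrate experiment digests a defined set of (mature) protein
#' substrates with the protease of interest, either alone
#' (`single_protease`) or followed by trypsin (`sequential_trypsin`) to
#' shorten otherwise too-long products for mass spectrometry. In sequential
#' mode, candidate sites attributable to the orthogonal enzyme are excluded
#' from the target profile.
#'
#' @param substrates Named list of [protein_record()] objects (mature
#'   forms; signal peptides pre-stripped with [mature_form()]).
#' @param mode `"single_protease"` or `"sequential_trypsin"`.
#' @param orthogonal An [enzyme_spec()] for the second-step enzyme
#'   (required in sequential mode; default [trypsin()]).
#' @param tag Experiment tag recorded on every site.
#' @return An object of class `substrate_experiment`.
#' @export
substrate_experiment <- function(substrates,
                                 mode = c("single_protease",
                                          "sequential_trypsin"),
                                 orthogonal = trypsin(), tag = mode[1]) {
  mode <- match.arg(mode)
  if (length(substrates) == 0) stop("substrate_experiment: no substrates")
  if (mode == "sequential_trypsin" && !inherits(orthogonal, "enzyme_spec"))
    stop("substrate_experiment: sequential mode requires an orthogonal enzyme")
  if (any(vapply(substrates, function(p) p$signal_peptide_length, integer(1)) > 0))
    stop("substrate_experiment: substrates must be mature forms ",
         "(apply mature_form() first)")
  structure(list(substrates = substrates, mode = mode,
                 orthogonal = orthogonal, tag = tag),
            class = "substrate_experiment")
}

#' Infer unique cleavage sites from a substrate digest
#'
#' Each mapped peptide contributes up to two candidate sites: one at its
#' amino terminus (P1 = start - 1) and one at its carboxy terminus
#' (P1 = end). Peptide termini coinciding with the substrate's own termini
#' contribute none. In `sequential_trypsin` mode, candidates whose P1
#' residue belongs to the orthogonal enzyme are attributed
#' `orthogonal_trypsin` and excluded from the target profile; in
#' `single_protease` mode all non-terminus candidates are target sites
#' (both ends are usable because no library enzyme is involved). Windows
#' are sliced from the mature substrate with X padding and deduplicated on
#' the window string.
#'
#' @param peptides Character vector of peptide sequences (or a data.frame
#'   with a `peptide` column).
#' @param experiment A [substrate_experiment()].
#' @return List with `sites` (as in [reconstruct_sites()], plus a `mode`
#'   column), `excluded` (data.frame of orthogonal-/terminus-attributed
#'   candidates) and `unmapped` (character vector of peptides that mapped
#'   to no substrate).
#' @export
infer_substrate_sites <- function(peptides, experiment) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(toupper(peptides))
  index <- proteome_index(experiment$substrates)
  rows <- list(); excluded <- list(); unmapped <- character()
  for (pep in peptides) {
    hits <- map_peptide(pep, index)
    if (nrow(hits) == 0) { unmapped <- c(unmapped, pep); next }
    for (j in seq_len(nrow(hits))) {
      prot <- hits$protein[j]
      pseq <- experiment$substrates[[prot]]$sequence
      plen <- nchar(pseq)
      cand <- data.frame(p1 = integer(), terminus = character())
      if (hits$start[j] > 1L)
        cand <- rbind(cand, data.frame(p1 = hits$start[j] - 1L,
                                       terminus = "N"))
      else
        excluded[[length(excluded) + 1L]] <- data.frame(
          peptide = pep, protein = prot, p1_position = 0L,
          attribution = "terminus")
      if (hits$end[j] < plen)
        cand <- rbind(cand, data.frame(p1 = hits$end[j], terminus = "C"))
      else
        excluded[[length(excluded) + 1L]] <- data.frame(
          peptide = pep, protein = prot, p1_position = plen,
          attribution = "terminus")
      for (k in seq_len(nrow(cand))) {
        p1 <- cand$p1[k]
        p1_res <- substr(pseq, p1, p1)
        if (experiment$mode == "sequential_trypsin" &&
            p1_res %in% experiment$orthogonal$p1_residues) {
          excluded[[length(excluded) + 1L]] <- data.frame(
            peptide = pep, protein = prot, p1_position = p1,
            attribution = "orthogonal_trypsin")
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          window = slice_window(pseq, p1), protein = prot,
          p1_position = p1, attribution = "target_protease")
      }
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(peptide = character(), protein = character(),
               p1_position = integer(), attribution = character())
  if (length(rows) == 0) {
    sites <- data.frame(window = character(), protein = character(),
                        p1_position = integer(), attribution = character(),
                        n_supporting_peptides = integer(),
                        experiment = character(), mode = character())
    return(list(sites = sites, excluded = excluded, unmapped = unmapped))
  }
  all_sites <- do.call(rbind, rows)
  agg <- aggregate(list(n_supporting_peptides = all_sites$window),
                   by = list(window = all_sites$window), FUN = length)
  first <- all_sites[!duplicated(all_sites$window), , drop = FALSE]
  sites <- merge(first, agg, by = "window", sort = TRUE)
  sites$experiment <- experiment$tag
  sites$mode <- experiment$mode
  sites <- sites[order(sites$protein, sites$p1_position), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, excluded = excluded, unmapped = unmapped)
}

#' Sequence coverage of a substrate by identified peptides
#'
#' Coverage is the union of all mapped peptide intervals over the mature
#' sequence length.
#'
#' @param peptides Character vector of peptide sequences (or data.frame
#'   with `peptide` column).
#' @param substrate A [protein_record()] (mature form).
#' @return An object of class `coverage_map`: list with `protein`,
#'   `covered` (logical vector), `fraction`.
#' @export
compute_coverage <- function(peptides, substrate) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  n <- nchar(substrate$sequence)
  covered <- rep(FALSE, n)
  index <- proteome_index(setNames(list(substrate), substrate$id))
  for (pep in unique(toupper(peptides))) {
    hits <- map_peptide(pep, index)
    for (j in seq_len(nrow(hits)))
      covered[hits$start[j]:hits$end[j]] <- TRUE
  }
  structure(list(protein = substrate$id, covered = covered,
                 fraction = sum(covered) / n,
                 sequence = substrate$sequence),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("coverage_map '%s': %.1f%% of %d residues\n", x$protein,
              100 * x$fraction, length(x$covered)))
  invisible(x)
}

#' Render a coverage map as text
#'
#' 60 residues per line; covered residues upper-case, uncovered lower-case.
#'
#' @param coverage A [compute_coverage()] result.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to `path`).
#' @export
format_coverage_map <- function(coverage, path = NULL) {
  chars <- strsplit(coverage$sequence, "")[[1]]
  chars <- ifelse(coverage$covered, toupper(chars), tolower(chars))
  starts <- seq(1, length(chars), by = 60)
  lines <- vapply(starts, function(s)
    paste(chars[s:min(s + 59, length(chars))], collapse = ""), character(1))
  header <- sprintf("> %s coverage %.4f", coverage$protein,
                    coverage$fraction)
  lines <- c(header, lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Unique-site set algebra across experiments
#'
#' Computes per-experiment unique window sets, all pairwise intersection
#' and union cardinalities, and the grand union.
#'
#' @param site_sets Named list; each element a site data.frame (with a
#'   `window` column) or a character vector of windows.
#' @return An object of class `site_set_summary`: list with `sets` (unique
#'   window vectors), `sizes`, `pairwise` (data.frame `a`, `b`,
#'   `intersection`, `union`), `grand_union`.
#' @export
site_set_algebra <- function(site_sets) {
  if (length(site_sets) == 0) stop("site_set_algebra: need at least one set")
  if (is.null(names(site_sets)) || any(!nzchar(names(site_sets))))
    stop("site_set_algebra: site_sets must be named")
  sets <- lapply(site_sets, function(s) {
    if (is.data.frame(s)) s <- s$window
    unique(as.character(s))
  })
  sizes <- vapply(sets, length, integer(1))
  tags <- names(sets)
  pairs <- if (length(sets) >= 2) utils::combn(tags, 2, simplify = FALSE)
           else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    i <- length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    u <- length(union(sets[[pr[1]]], sets[[pr[2]]]))
    data.frame(a = pr[1], b = pr[2], intersection = i, union = u)
  }))
  if (is.null(pairwise))
    pairwise <- data.frame(a = character(), b = character(),
                           intersection = integer(), union = integer())
  structure(list(sets = sets, sizes = sizes, pairwise = pairwise,
                 grand_union = length(unique(unlist(sets)))),
            class = "site_set_summary")
}

#' @export
print.site_set_summary <- function(x, ...) {
  cat("site_set_summary:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                                 collapse = ", "),
      sprintf("; grand union %d\n", x$grand_union))
  invisible(x)
}

#' Cleavage-site density per named protein region
#'
#' A site belongs to the region containing its P1 position. Regions of the
#' same protein must not overlap.
#'
#' @param sites Site data.frame (`protein`, `p1_position`).
#' @param regions Data.frame with `protein`, `name`, `start`, `end`
#'   (1-based inclusive).
#' @return Data.frame with `protein`, `name`, `start`, `end`, `n_sites`,
#'   `density` (sites per residue).
#' @export
region_density <- function(sites, regions) {
  required <- c("protein", "name", "start", "end")
  if (!all(required %in% names(regions)))
    stop("region_density: regions need columns ",
         paste(required, collapse = ", "))
  for (prot in unique(regions$protein)) {
    r <- regions[regions$protein == prot, , drop = FALSE]
    if (nrow(r) > 1) {
      r <- r[order(r$start), , drop = FALSE]
      if (any(r$start[-1] <= r$end[-nrow(r)]))
        stop("region_density: overlapping regions for protein ", prot)
    }
  }
  regions$n_sites <- vapply(seq_len(nrow(regions)), function(i)
    sum(sites$protein == regions$protein[i] &
          sites$p1_position >= regions$start[i] &
          sites$p1_position <= regions$end[i]), integer(1))
  regions$density <- regions$n_sites / (regions$end - regions$start + 1)
  regions
}

#' Summarise a site-set comparison as JSON
#'
#' @param summary A [site_set_algebra()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_set_summary <- function(summary, path) {
  jsonlite::write_json(list(sizes = as.list(summary$sizes),
                            pairwise = summary$pairwise,
                            grand_union = summary$grand_union),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
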