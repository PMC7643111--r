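#' Count subsite occurrences over a set of cleavage windows
#'
#' Builds the 20 x 12 count matrix underlying the specificity heat maps:
#' rows are the standard residues (alphabetical), columns the subsites
#' P6..P6'. X-padded window cells are skipped and the per-subsite countable
#' totals reduced accordingly.
#'
#' @param sites Site data.frame with a `window` column, or a character
#'   vector of 12-letter windows.
#' @return Integer matrix of class `subsite_matrix` with attribute
#'   `totals` (countable positions per subsite) and `n_sites`.
#' @export
build_subsite_matrix <- function(sites) {
  windows <- if (is.data.frame(sites)) sites$window else as.character(sites)
  if (any(nchar(windows) != 12)) {
    bad <- which(nchar(windows) != 12)[1]
    stop("build_subsite_matrix: window of wrong length at site ", bad,
         " ('", windows[bad], "')")
  }
  counts <- matrix(0L, nrow = 20, ncol = 12,
                   dimnames = list(AA_STANDARD, SUBSITES))
  if (length(windows) > 0) {
    chars <- matrix(unlist(strsplit(windows, "")), ncol = 12, byrow = TRUE)
    for (s in seq_len(12)) {
      tab <- table(factor(chars[, s], levels = AA_STANDARD))
      counts[, s] <- as.integer(tab)
    }
  }
  structure(counts, class = c("subsite_matrix", class(counts)),
            totals = colSums(counts), n_sites = length(windows))
}

#' Relative occurrence per subsite
#'
#' Column-stochastic normalisation of the subsite counts: cell = count /
#' countable total of its subsite. Subsites with no countable residues emit
#' an all-zero column and are flagged undefined.
#'
#' @param matrix A [build_subsite_matrix()] result.
#' @return Numeric 20 x 12 matrix with attribute `undefined` (logical per
#'   subsite).
#' @export
relative_occurrence <- function(matrix) {
  totals <- attr(matrix, "totals")
  out <- sweep(unclass(matrix), 2, pmax(totals, 1L), "/")
  out[, totals == 0] <- 0
  attr(out, "undefined") <- totals == 0
  out
}

#' Fold enrichment over natural abundance
#'
#' Ratio of a residue's observed subsite frequency to its background
#' frequency. By default no pseudocount is applied so the ratios are plain
#' (unobserved residues give 0, to be marked rather than smoothed); a
#' symmetric pseudocount added to every count before normalisation is
#' available for small site sets.
#'
#' @param matrix A [build_subsite_matrix()] result.
#' @param background A [background_frequencies()] vector.
#' @param pseudocount Added to all counts before normalisation (default 0).
#' @return Numeric 20 x 12 ratio matrix; cells with zero background are 0
#'   and flagged in attribute `undefined_cells`.
#' @export
fold_enrichment <- function(matrix, background, pseudocount = 0) {
  if (!all(AA_STANDARD %in% names(background)))
    stop("fold_enrichment: background is missing residue(s): ",
         paste(setdiff(AA_STANDARD, names(background)), collapse = ", "))
  bg <- as.numeric(background[AA_STANDARD])
  counts <- unclass(matrix) + pseudocount
  totals <- colSums(counts)
  occ <- sweep(counts, 2, pmax(totals, .Machine$double.eps), "/")
  occ[, totals == 0] <- 0
  ratio <- sweep(occ, 1, ifelse(bg > 0, bg, 1), "/")
  undefined <- matrix(rep(bg == 0, 12), nrow = 20)
  ratio[undefined] <- 0
  attr(ratio, "undefined_cells") <- undefined
  ratio
}

#' Percent-difference profile with per-cell significance
#'
#' The iceLogo-style statistic: for each residue and subsite, the
#' difference between observed and background frequency in percentage
#' points, with a two-sided one-sample z-test of the observed proportion
#' against the background (`se = sqrt(p_bg (1 - p_bg) / N)`, N the
#' subsite's countable total). No multiple-testing correction is applied by
#' default, matching the logo tool this emulates; `correct = "bonferroni"`
#' is available.
#'
#' @param matrix A [build_subsite_matrix()] result.
#' @param background A [background_frequencies()] vector.
#' @param alpha Significance level in (0, 1).
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return List with `difference` (percentage points, 20 x 12),
#'   `p_value`, `significant` (logical mask at `alpha`), `low_information`
#'   (cells with expected count below 1), `undefined` (subsites with N =
#'   0), `alpha`.
#' @export
icelogo_difference <- function(matrix, background, alpha = 0.05,
                               correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  if (alpha <= 0 || alpha >= 1) stop("icelogo_difference: alpha must be in (0, 1)")
  bg <- as.numeric(background[AA_STANDARD])
  totals <- attr(matrix, "totals")
  occ <- relative_occurrence(matrix)
  diff <- 100 * sweep(occ, 1, bg, "-")
  diff[, totals == 0] <- 0
  se <- sqrt(outer(bg * (1 - bg), pmax(totals, 1L), "/"))
  z <- (occ - bg) / ifelse(se > 0, se, Inf)
  p <- 2 * pnorm(-abs(z))
  p[, totals == 0] <- NA_real_
  if (correct == "bonferroni")
    p <- matrix(p.adjust(p, method = "bonferroni"), nrow = 20,
                dimnames = dimnames(p))
  significant <- !is.na(p) & p < alpha
  low_info <- outer(bg, totals, function(b, n) b * n < 1)
  dn <- list(AA_STANDARD, SUBSITES)
  diff <- matrix(as.numeric(diff), 20, 12, dimnames = dn)
  p <- matrix(as.numeric(p), 20, 12, dimnames = dn)
  significant <- matrix(as.logical(significant), 20, 12, dimnames = dn)
  low_info <- matrix(as.logical(low_info), 20, 12, dimnames = dn)
  list(difference = diff, p_value = p, significant = significant,
       low_information = low_info, undefined = totals == 0, alpha = alpha)
}

#' Full specificity profile of a cleavage-site set
#'
#' Bundles the three statistics reported for a specificity experiment:
#' relative occurrence, fold enrichment over natural abundance, and the
#' percent-difference profile with significance.
#'
#' @param sites Site data.frame or character vector of windows.
#' @param background A [background_frequencies()] vector.
#' @param alpha Significance level (default 0.05).
#' @param pseudocount Passed to [fold_enrichment()].
#' @return An object of class `specificity_profile`.
#' @export
specificity_profile <- function(sites, background, alpha = 0.05,
                                pseudocount = 0) {
  m <- build_subsite_matrix(sites)
  if (attr(m, "n_sites") == 0)
    warning("specificity_profile: no sites; matrices are all zero")
  logo <- icelogo_difference(m, background, alpha = alpha)
  structure(list(counts = m,
                 occurrence = relative_occurrence(m),
                 enrichment = fold_enrichment(m, background, pseudocount),
                 difference = logo$difference,
                 p_value = logo$p_value,
                 significant = logo$significant,
                 low_information = logo$low_information,
                 n_sites = attr(m, "n_sites"),
                 subsite_totals = attr(m, "totals"),
                 background = as.numeric(background[AA_STANDARD]),
                 background_id = attr(background, "proteome_id"),
                 alpha = alpha),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf("specificity_profile: %d sites, background '%s', alpha %g\n",
              x$n_sites, x$background_id %||% "custom", x$alpha))
  p1p <- sort(x$enrichment[, "P1'"], decreasing = TRUE)[1:3]
  cat("  top P1' fold enrichment:",
      paste(sprintf("%s=%.2f", names(p1p), p1p), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a specificity profile
#'
#' Writes one TSV per matrix (20 residue rows in fixed alphabetical order,
#' 12 subsite columns) and a JSON bundle containing all matrices plus
#' metadata; the JSON round-trips losslessly through [read_profile()].
#'
#' @param profile A [specificity_profile()].
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_profile <- function(profile, out_dir, prefix = "profile") {
  if (profile$n_sites == 0)
    stop("export_profile: profile is empty (no sites)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(mat, name) {
    path <- file.path(out_dir, sprintf("%s_%s.tsv", prefix, name))
    df <- data.frame(residue = rownames(mat), as.data.frame(unclass(mat)),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(write_mat(profile$counts, "counts"),
             write_mat(profile$occurrence, "occurrence"),
             write_mat(profile$enrichment, "fold_enrichment"),
             write_mat(profile$difference, "percent_difference"))
  json_path <- file.path(out_dir, sprintf("%s.json", prefix))
  bundle <- list(
    n_sites = profile$n_sites,
    alpha = profile$alpha,
    background_id = profile$background_id %||% "custom",
    subsites = SUBSITES, residues = AA_STANDARD,
    subsite_totals = as.numeric(profile$subsite_totals),
    background = profile$background,
    counts = unclass(profile$counts),
    occurrence = unclass(profile$occurrence),
    enrichment = unclass(profile$enrichment),
    difference = unclass(profile$difference),
    p_value = unclass(profile$p_value),
    significant = unclass(profile$significant))
  jsonlite::write_json(bundle, json_path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(c(paths, json_path))
}

#' Re-import a profile JSON bundle
#'
#' @param path Path to a JSON file written by [export_profile()].
#' @return List of matrices and metadata, numerically identical to the
#'   exported profile.
#' @export
read_profile <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(AA_STANDARD, SUBSITES)
    m
  }
  for (nm in c("counts", "occurrence", "enrichment", "difference",
               "p_value", "significant"))
    b[[nm]] <- fix(b[[nm]])
  b
}
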