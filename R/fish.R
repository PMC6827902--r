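# Radial position statistics for 3D-FISH allele coordinates. The nucleus is
# modeled as a sphere (center + radius, micrometres); an allele's normalized
# distance ND = (R - r)/R maps the periphery to 0 and the center to 1, and
# NDs are histogrammed into ten fixed shells [0,0.1), ..., [0.9,1].

SHELL_BREAKS <- seq(0, 1, by = 0.1)

.check_nuclei <- function(nuclei) {
  need <- c("nucleus_id", "center_x", "center_y", "center_z", "radius")
  miss <- setdiff(need, names(nuclei))
  if (length(miss)) stop("nuclei table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(nuclei$nucleus_id)) stop("duplicate nucleus_id")
  if (any(nuclei$radius <= 0)) stop("all nuclear radii must be > 0")
  nuclei
}

.check_alleles <- function(alleles) {
  need <- c("nucleus_id", "allele_x", "allele_y", "allele_z")
  miss <- setdiff(need, names(alleles))
  if (length(miss)) stop("allele table missing columns: ",
                         paste(miss, collapse = ", "))
  alleles
}

#' Radius-normalized distance of alleles to the nuclear edge
#'
#' For each allele, nd = (radius - |position - center|) / radius for its own
#' nucleus, so differently sized nuclei become comparable. Alleles slightly
#' outside the sphere (segmentation noise, up to `tolerance` of the radius)
#' are clamped to nd = 0; farther outside is a validation error.
#'
#' @param alleles data.frame with nucleus_id, allele_x/y/z (and any further
#'   columns, e.g. locus, expressed, lamina_contact — carried through).
#' @param nuclei data.frame with nucleus_id, center_x/y/z, radius.
#' @param tolerance allowed relative excursion outside the sphere (default
#'   0.02).
#' @return the allele table with `nd` (in \[0,1\]) and `shell` (0-9) added.
#' @export
normalized_distance <- function(alleles, nuclei, tolerance = 0.02) {
  nuclei <- .check_nuclei(nuclei)
  alleles <- .check_alleles(alleles)
  i <- match(alleles$nucleus_id, nuclei$nucleus_id)
  if (anyNA(i)) stop("allele references unknown nucleus: ",
                     alleles$nucleus_id[which(is.na(i))[1]])
  r <- sqrt((alleles$allele_x - nuclei$center_x[i])^2 +
            (alleles$allele_y - nuclei$center_y[i])^2 +
            (alleles$allele_z - nuclei$center_z[i])^2)
  R <- nuclei$radius[i]
  if (any(r > R * (1 + tolerance)))
    stop("validation error: allele lies outside the nuclear sphere beyond tolerance")
  nd <- pmin(pmax((R - r) / R, 0), 1)
  alleles$nd <- nd
  alleles$shell <- shell_of(nd)
  alleles
}

#' Shell index (0-9) of a normalized distance
#' @param nd numeric in \[0,1\].
#' @return integer shell per the fixed edges, final bin closed at 1.
#' @export
shell_of <- function(nd) {
  if (any(nd < 0 | nd > 1)) stop("nd must lie in [0, 1]")
  as.integer(pmin(floor(nd * 10), 9))
}

#' Concentric-shell histogram of normalized distances
#'
#' @param nd numeric vector of ND values, or a data.frame with an `nd`
#'   column (e.g. from [normalized_distance()]).
#' @return list of class `shell_histogram`: `counts` and `fractions` (length
#'   10, shells 0-9 from periphery to center), `n`, `breaks`.
#' @export
shell_histogram <- function(nd) {
  if (is.data.frame(nd)) nd <- nd$nd
  if (length(nd) == 0) stop("empty input")
  sh <- shell_of(nd)
  counts <- tabulate(sh + 1L, nbins = 10L)
  structure(list(counts = counts, fractions = counts / length(nd),
                 n = length(nd), breaks = SHELL_BREAKS),
            class = "shell_histogram")
}

#' @export
print.shell_histogram <- function(x, ...) {
  cat(sprintf("shell histogram of %d alleles (shell 0 = periphery)\n", x$n))
  print(setNames(round(x$fractions, 3),
                 sprintf("%.1f-%.1f", head(x$breaks, -1), tail(x$breaks, -1))))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of ND distributions
#'
#' Two-sided two-sample KS test; exact p-value when both samples have at
#' most 25 observations and there are no ties, asymptotic otherwise. The
#' result is additionally flagged against the conventional imaging
#' significance threshold p < 1e-4.
#'
#' @param sample_a,sample_b numeric vectors, each of size >= 2.
#' @param alpha significance threshold for the `significant` flag.
#' @return list with `D`, `p.value`, `significant`, `n_a`, `n_b`.
#' @export
ks_compare <- function(sample_a, sample_b, alpha = 1e-4) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples must have size >= 2")
  exact <- length(sample_a) <= 25 && length(sample_b) <= 25 &&
    anyDuplicated(c(sample_a, sample_b)) == 0
  ht <- suppressWarnings(ks.test(sample_a, sample_b,
                                 alternative = "two.sided", exact = exact))
  list(D = unname(ht$statistic), p.value = ht$p.value,
       significant = ht$p.value < alpha,
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Lamina colocalization fractions
#'
#' An allele is called lamina-associated from the imaging-derived
#' `lamina_contact` flag when present; for alleles without a flag the call
#' falls back to a peripheral-shell criterion: distance to the nuclear
#' surface <= `shell_thickness` (micrometres, or a fraction of the radius
#' with `unit = "fraction"`), a documented stand-in for the pixel-overlap
#' criterion used on images.
#'
#' @param alleles allele data.frame (see [normalized_distance()]);
#'   `expressed` and `lamina_contact` columns are used when present.
#' @param nuclei nucleus data.frame.
#' @param shell_thickness numeric contact threshold (default 0.1 um).
#' @param unit "um" or "fraction".
#' @return list: `frac_alleles` (alleles colocalized), `frac_cells` (cells
#'   with >= 1 colocalized allele), `frac_expressed_alleles` (among expressed
#'   alleles only; NA if none expressed), `n_alleles`, `n_cells`.
#' @export
lamina_colocalization <- function(alleles, nuclei, shell_thickness = 0.1,
                                  unit = c("um", "fraction")) {
  unit <- match.arg(unit)
  nuclei <- .check_nuclei(nuclei)
  alleles <- .check_alleles(alleles)
  i <- match(alleles$nucleus_id, nuclei$nucleus_id)
  if (anyNA(i)) stop("allele references unknown nucleus")
  r <- sqrt((alleles$allele_x - nuclei$center_x[i])^2 +
            (alleles$allele_y - nuclei$center_y[i])^2 +
            (alleles$allele_z - nuclei$center_z[i])^2)
  R <- nuclei$radius[i]
  edge <- pmax(R - r, 0)
  thr <- if (unit == "um") shell_thickness else shell_thickness * R
  contact <- edge <= thr
  if (!is.null(alleles$lamina_contact)) {
    flag <- as.logical(alleles$lamina_contact)
    contact[!is.na(flag)] <- flag[!is.na(flag)]
  }
  per_cell <- tapply(contact, alleles$nucleus_id, any)
  expressed <- if (is.null(alleles$expressed)) rep(FALSE, nrow(alleles))
               else as.logical(alleles$expressed)
  list(frac_alleles = mean(contact),
       frac_cells = mean(per_cell),
       frac_expressed_alleles = if (any(expressed))
         mean(contact[expressed]) else NA_real_,
       n_alleles = nrow(alleles), n_cells = length(per_cell))
}

#' Mono-/biallelic expression summary per cell
#'
#' Classifies each nucleus by the number of expressed alleles of a locus
#' (0 = silent, 1 = monoallelic, 2 = biallelic). Fractions are reported with
#' two denominators: over all cells and over cells expressing at least one
#' allele (both are used in practice and the intended one is not always the
#' same).
#'
#' @param alleles data.frame with nucleus_id, locus, expressed.
#' @return data.frame, one row per locus: n_cells, n_mono, n_bi, n_silent
#'   and the fractions on both denominators.
#' @export
allelic_summary <- function(alleles) {
  need <- c("nucleus_id", "locus", "expressed")
  miss <- setdiff(need, names(alleles))
  if (length(miss)) stop("allele table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(alleles$nucleus_id, alleles$locus, sep = "\r")
  n_per <- table(key)
  if (any(n_per > 2))
    stop("validation error: more than 2 alleles for one locus in one nucleus")
  expr_count <- tapply(as.logical(alleles$expressed), key, sum)
  locus_of <- tapply(as.character(alleles$locus), key, `[`, 1L)
  groups <- split(expr_count, unname(locus_of))
  out <- do.call(rbind, lapply(names(groups), function(loc) {
    ec <- groups[[loc]]
    n_cells <- length(ec)
    n_mono <- sum(ec == 1); n_bi <- sum(ec == 2); n_silent <- sum(ec == 0)
    n_expr <- n_mono + n_bi
    data.frame(locus = loc, n_cells = n_cells, n_mono = n_mono,
               n_bi = n_bi, n_silent = n_silent,
               frac_mono_all = n_mono / n_cells,
               frac_bi_all = n_bi / n_cells,
               frac_silent_all = n_silent / n_cells,
               frac_mono_expressing = if (n_expr) n_mono / n_expr else NA_real_,
               frac_bi_expressing = if (n_expr) n_bi / n_expr else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare ND distributions of expressed vs silent alleles
#'
#' @param nds data.frame with `nd` and `expressed` columns (e.g. the output
#'   of [normalized_distance()]).
#' @return list with the two ND samples, their shell histograms, medians and
#'   the [ks_compare()] result.
#' @export
expressed_vs_silent_nd <- function(nds) {
  if (is.null(nds$nd) || is.null(nds$expressed))
    stop("input must have nd and expressed columns")
  expr <- nds$nd[as.logical(nds$expressed)]
  silent <- nds$nd[!as.logical(nds$expressed)]
  if (length(expr) == 0 || length(silent) == 0)
    stop("both expressed and silent groups must be non-empty")
  list(expressed = expr, silent = silent,
       hist_expressed = shell_histogram(expr),
       hist_silent = shell_histogram(silent),
       median_expressed = median(expr), median_silent = median(silent),
       ks = ks_compare(expr, silent))
}

#' Read a per-allele coordinate table
#'
#' One flat TSV row per allele with the nucleus geometry repeated:
#' nucleus_id, cell_type, condition, center_x/y/z, radius, locus,
#' allele_x/y/z, expressed, lamina_contact (last two optional).
#'
#' @param path TSV path.
#' @return list with `nuclei` (one row per nucleus) and `alleles`
#'   data.frames.
#' @export
read_allele_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  .check_nuclei(tab[!duplicated(tab$nucleus_id), , drop = FALSE])
  nuc_cols <- intersect(c("nucleus_id", "cell_type", "condition",
                          "center_x", "center_y", "center_z", "radius"),
                        names(tab))
  nuclei <- tab[!duplicated(tab$nucleus_id), nuc_cols, drop = FALSE]
  rownames(nuclei) <- NULL
  al_cols <- setdiff(names(tab), setdiff(nuc_cols, "nucleus_id"))
  alleles <- tab[, al_cols, drop = FALSE]
  list(nuclei = nuclei, alleles = .check_alleles(alleles))
}

#' Write a per-allele coordinate table
#' @param nuclei,alleles data.frames as returned by [generate_nuclei()].
#' @param path output TSV path.
#' @export
write_allele_table <- function(nuclei, alleles, path) {
  i <- match(alleles$nucleus_id, nuclei$nucleus_id)
  if (anyNA(i)) stop("allele references unknown nucleus")
  flat <- cbind(nuclei[i, , drop = FALSE],
                alleles[, setdiff(names(alleles), "nucleus_id"), drop = FALSE])
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
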