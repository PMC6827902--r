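# Coordinate convention: every file boundary (BED, chrom.sizes, bedGraph,
# TSV output) is 0-based half-open. In memory intervals are GRanges (1-based
# closed); the shift happens exactly once, in the readers/writers here.

#' Normalize chromosome names to the "chr" prefix dialect
#'
#' @param x character vector of chromosome names ("1" and "chr1" both map to
#'   "chr1").
#' @return character vector.
#' @export
norm_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Build a genome assembly (chromosome-size universe)
#'
#' The assembly fixes the universe over which shuffles, coverage fractions
#' and bounds checks are computed.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp).
#' @param build optional build label (e.g. "mm9", "hg19").
#' @return a [GenomeInfoDb::Seqinfo] object.
#' @export
genome_assembly <- function(chrom_lengths, build = NA_character_) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) == 0)
    stop("chrom_lengths must be a non-empty numeric vector")
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("chromosome names must be present and unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  GenomeInfoDb::Seqinfo(seqnames = norm_chrom(nm),
                        seqlengths = as.integer(chrom_lengths),
                        genome = build)
}

#' Read a two-column chrom.sizes table
#'
#' @param path path to a TSV with columns chromosome, length.
#' @param build optional build label.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
read_chrom_sizes <- function(path, build = NA_character_) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric"))
  genome_assembly(setNames(tab[[2]], tab[[1]]), build = build)
}

#' Write an assembly as a chrom.sizes file
#' @param assembly a Seqinfo.
#' @param path output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  write.table(data.frame(GenomeInfoDb::seqnames(assembly),
                         GenomeInfoDb::seqlengths(assembly)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_size <- function(assembly) {
  sl <- GenomeInfoDb::seqlengths(assembly)
  if (length(sl) == 0 || anyNA(sl)) stop("assembly has no chromosome lengths")
  sum(as.numeric(sl))
}

#' Read a BED file into a GRanges
#'
#' BED semantics: tab-separated, >= 3 columns, 0-based half-open coordinates.
#' Optional columns 4 (name) and 6 (strand) are kept. Chromosome names are
#' normalized to the "chr" prefix. With `one_based = TRUE` the input is
#' treated as 1-based inclusive (GFF-style coordinate lists) and shifted at
#' read time.
#'
#' @param path file path.
#' @param assembly optional [GenomeInfoDb::Seqinfo]; when supplied, unknown
#'   chromosomes and records exceeding chromosome bounds are errors.
#' @param one_based logical; input start coordinates are 1-based inclusive.
#' @return a [GenomicRanges::GRanges] in file order.
#' @export
read_bed <- function(path, assembly = NULL, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) {
    gr <- GRanges()
    if (!is.null(assembly)) GenomeInfoDb::seqinfo(gr) <- assembly
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("parse error at line %d: expected >= 3 tab-separated columns",
                 lineno[which(nf < 3)[1]]))
  chrom <- norm_chrom(vapply(fields, `[[`, "", 1L))
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-numeric coordinates", lineno[bad[1]]))
  if (one_based) start <- start - 1
  bad <- which(start < 0)
  if (length(bad))
    stop(sprintf("parse error at line %d: negative start", lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("parse error at line %d: start >= end", lineno[bad[1]]))
  nm <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  nm[nm == "." | nf < 4] <- NA_character_
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (!is.null(assembly)) {
    known <- GenomeInfoDb::seqnames(assembly)
    bad <- which(!chrom %in% known)
    if (length(bad))
      stop(sprintf("validation error at line %d: unknown chromosome '%s'",
                   lineno[bad[1]], chrom[bad[1]]))
    sl <- GenomeInfoDb::seqlengths(assembly)
    bad <- which(end > sl[chrom])
    if (length(bad))
      stop(sprintf("validation error at line %d: interval exceeds chromosome bounds",
                   lineno[bad[1]]))
  }
  gr <- GRanges(seqnames = if (is.null(assembly)) chrom else
                  factor(chrom, levels = GenomeInfoDb::seqnames(assembly)),
                ranges = IRanges(start = start + 1, end = end),
                strand = strand)
  if (!is.null(assembly)) GenomeInfoDb::seqinfo(gr) <- assembly
  if (any(!is.na(nm))) names(gr) <- nm
  gr
}

#' Read feature coordinates from a GFF3 file
#'
#' Intended for miRBase precursor annotation: only seqid, start, end and the
#' `Name` attribute are consumed. GFF3 is 1-based inclusive; coordinates are
#' converted internally.
#'
#' @param path GFF3 file path.
#' @param assembly optional Seqinfo for validation.
#' @param type feature type(s) to keep (default miRBase precursor records);
#'   `NULL` keeps everything.
#' @return a GRanges named by the `Name` attribute where present.
#' @export
read_feature_gff <- function(path, assembly = NULL,
                             type = "miRNA_primary_transcript") {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(type) && "type" %in% names(mcols(gr)))
    gr <- gr[as.character(gr$type) %in% type]
  nm <- if ("Name" %in% names(mcols(gr))) as.character(gr$Name) else NULL
  out <- GRanges(norm_chrom(as.character(seqnames(gr))), ranges(gr),
                 strand = strand(gr))
  if (!is.null(nm)) names(out) <- nm
  if (!is.null(assembly)) {
    known <- GenomeInfoDb::seqnames(assembly)
    if (any(!as.character(seqnames(out)) %in% known))
      stop("validation error: unknown chromosome in GFF input")
    out <- GRanges(factor(as.character(seqnames(out)), levels = known),
                   ranges(out), strand = strand(out), seqinfo = assembly)
    if (!is.null(nm)) names(out) <- nm
  }
  out
}

#' Write intervals to a BED file
#'
#' @param x GRanges or domain_set.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  gr <- as_ranges(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = if (is.null(names(gr))) "." else names(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_ranges <- function(x) {
  if (inherits(x, "domain_set")) x$ranges
  else if (is(x, "GRanges")) x
  else stop("expected a GRanges or domain_set")
}

#' Merge intervals into a sorted non-overlapping union
#'
#' Overlapping and book-ended (end == start) intervals are unioned; strand is
#' ignored.
#'
#' @param x GRanges.
#' @return sorted, disjoint, unstranded GRanges covering the same base pairs.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(as_ranges(x), ignore.strand = TRUE)
}

#' Total base pairs shared by two interval sets
#'
#' Computes the width of the intersection of the two unions; symmetric in its
#' arguments and independent of strand.
#'
#' @param a,b GRanges or domain_set.
#' @return numeric, intersected base pairs.
#' @export
overlap_bp <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- sl
  GenomeInfoDb::seqlevels(b) <- sl
  sum(as.numeric(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
}

#' Subset features that fall in a domain set
#'
#' Membership rule "any": a feature belongs if it shares >= 1 bp with any
#' domain interval. Rule "midpoint": the base pair containing the feature
#' midpoint must lie inside a domain. Both modes are exposed because printed
#' per-chromosome tallies in the field use either convention.
#'
#' @param features GRanges.
#' @param domains GRanges or domain_set.
#' @param mode "any" (default) or "midpoint".
#' @return the subset of `features`, original order and metadata preserved.
#' @export
features_overlapping <- function(features, domains, mode = c("any", "midpoint")) {
  mode <- match.arg(mode)
  dom <- merge_intervals(domains)
  sl <- union(GenomeInfoDb::seqlevels(features), GenomeInfoDb::seqlevels(dom))
  GenomeInfoDb::seqlevels(dom) <- sl
  qry <- features
  GenomeInfoDb::seqlevels(qry) <- sl
  if (mode == "midpoint") {
    mid0 <- floor((start(qry) - 1 + end(qry)) / 2)  # 0-based bp index
    qry <- GRanges(seqnames(qry), IRanges(mid0 + 1, width = 1))
  }
  hit <- overlapsAny(qry, dom, ignore.strand = TRUE)
  features[hit]
}

#' Labeled non-overlapping domain collection
#'
#' A `domain_set` wraps a merged GRanges (e.g. cLADs, ciLADs or nucleoporin
#' peaks) together with a label and the assembly it lives on.
#'
#' @param ranges GRanges of domain intervals (merged internally).
#' @param label character label (e.g. "cLAD").
#' @param assembly a Seqinfo; required for coverage fractions and shuffling.
#' @return an object of class `domain_set`.
#' @export
domain_set <- function(ranges, label, assembly = NULL) {
  gr <- merge_intervals(ranges)
  if (!is.null(assembly)) {
    known <- GenomeInfoDb::seqnames(assembly)
    if (any(!as.character(seqnames(gr)) %in% known))
      stop("domain interval on a chromosome absent from the assembly")
    sl <- GenomeInfoDb::seqlengths(assembly)
    if (any(end(gr) > sl[as.character(seqnames(gr))]))
      stop("domain interval exceeds chromosome bounds")
    gr <- sort(GRanges(factor(as.character(seqnames(gr)), levels = known),
                       ranges(gr), seqinfo = assembly))
  } else {
    assembly <- GenomeInfoDb::seqinfo(gr)
  }
  structure(list(label = label, ranges = gr, assembly = assembly),
            class = "domain_set")
}

#' Fraction of the genome covered by a domain set
#' @param x a domain_set.
#' @return numeric in \[0, 1\].
#' @export
coverage_fraction <- function(x) {
  x <- if (inherits(x, "domain_set")) x else domain_set(x, label = "domains")
  sum(as.numeric(width(x$ranges))) / genome_size(x$assembly)
}

#' @export
print.domain_set <- function(x, ...) {
  cov <- tryCatch(coverage_fraction(x), error = function(e) NA_real_)
  cat(sprintf("domain_set '%s': %d intervals%s\n", x$label, length(x$ranges),
              if (is.na(cov)) "" else sprintf(", %.1f%% genome coverage", 100 * cov)))
  invisible(x)
}
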