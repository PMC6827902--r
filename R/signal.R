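# Expression evidence over loci: mean aggregate score of a bedGraph-style
# signal track, and constitutive/tissue-specific gene calls from an
# expression (RPKM-like) matrix.

#' Read a bedGraph signal track
#'
#' Four columns (chrom, start, end, value), 0-based half-open. Intervals
#' within a chromosome must not overlap.
#'
#' @param path bedGraph path.
#' @return data.frame of class `signal_track`.
#' @export
read_bedgraph <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "value"),
                    colClasses = c("character", "numeric", "numeric", "numeric"))
  signal_track(tab)
}

#' Construct a signal track from a data.frame
#'
#' @param x data.frame with columns chrom, start, end, value (0-based
#'   half-open intervals).
#' @return validated data.frame of class `signal_track`.
#' @export
signal_track <- function(x) {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(x))) stop("signal track needs columns ",
                                     paste(need, collapse = ", "))
  if (any(!is.finite(x$value))) stop("signal values must be finite")
  if (any(x$start >= x$end)) stop("signal interval with start >= end")
  x$chrom <- norm_chrom(x$chrom)
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  ov <- unlist(tapply(seq_len(nrow(x)), x$chrom, function(i) {
    if (length(i) < 2) return(FALSE)
    any(x$start[i][-1] < x$end[i][-length(i)])
  }))
  if (any(ov)) stop("overlapping intervals within a chromosome")
  rownames(x) <- NULL
  class(x) <- c("signal_track", "data.frame")
  x
}

#' Mean aggregate signal score over a locus
#'
#' Length-weighted mean of the track value across the locus span; base
#' pairs not covered by the track contribute 0 (bigWig-style aggregate
#' convention). A locus on a chromosome absent from the track scores 0 with
#' a warning.
#'
#' @param track a `signal_track`.
#' @param loci GRanges (one score per range).
#' @return numeric vector of mean scores.
#' @export
aggregate_score <- function(track, loci) {
  if (!inherits(track, "signal_track")) track <- signal_track(track)
  if (any(width(loci) == 0)) stop("zero-length locus")
  ch <- norm_chrom(as.character(seqnames(loci)))
  s0 <- start(loci) - 1; e0 <- end(loci)
  vapply(seq_along(loci), function(i) {
    rows <- track$chrom == ch[i]
    if (!any(rows)) {
      warning("locus chromosome ", ch[i], " absent from track; score 0")
      return(0)
    }
    ov <- pmin(track$end[rows], e0[i]) - pmax(track$start[rows], s0[i])
    sum(track$value[rows] * pmax(ov, 0)) / (e0[i] - s0[i])
  }, numeric(1))
}

#' Classify genes as constitutive / tissue-specific / neither
#'
#' Two published rules are implemented. `human32` expects 32 tissue columns
#' and a per-gene/tissue high-expression indicator: a gene highly expressed
#' in >= 80% of tissues is constitutive, in < 10% tissue-specific, otherwise
#' neither. The indicator can be supplied directly (`high`, a logical
#' matrix) or is derived from the values by a per-tissue quantile threshold
#' (`high_fraction`, default top 50% — a configurable stand-in for external
#' expression-atlas calls). `mouse6` expects 6 tissue columns and calls
#' constitutive the genes in the top decile of every tissue's expression
#' ranking (ties at the cutoff included); it makes no tissue-specific call.
#'
#' @param expr numeric matrix/data.frame, genes x tissues, rownames = gene
#'   ids.
#' @param rule "human32" or "mouse6".
#' @param high optional logical matrix (same shape) of high-expression calls.
#' @param high_fraction fraction of each tissue's genes counted as highly
#'   expressed when deriving the indicator (human32 only).
#' @return named character vector of labels.
#' @export
classify_genes <- function(expr, rule = c("human32", "mouse6"),
                           high = NULL, high_fraction = 0.5) {
  rule <- match.arg(rule)
  expr <- as.matrix(expr)
  want <- if (rule == "human32") 32L else 6L
  if (ncol(expr) != want)
    stop(sprintf("rule %s expects %d tissue columns, got %d",
                 rule, want, ncol(expr)))
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(expr)))
  if (rule == "human32") {
    if (is.null(high)) {
      if (is.logical(expr)) high <- expr
      else high <- apply(expr, 2, function(v) v >= quantile(v, 1 - high_fraction))
    }
    high <- as.matrix(high)
    if (!identical(dim(high), dim(expr)))
      stop("high indicator must match the expression matrix shape")
    frac <- rowMeans(high)
    lab <- ifelse(frac >= 0.8, "constitutive",
                  ifelse(frac < 0.1, "tissue_specific", "neither"))
  } else {
    top <- apply(expr, 2, function(v) v >= quantile(v, 0.9))
    lab <- ifelse(rowSums(top) == ncol(expr), "constitutive", "neither")
  }
  setNames(lab, genes)
}
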