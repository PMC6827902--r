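# Independent brute-force oracles used to cross-check the interval,
# enrichment, boundary and statistics code paths. These deliberately avoid
# the package's own data structures: intervals become per-bp boolean masks
# on toy chromosomes, and test statistics are obtained by full enumeration.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

toy_assembly <- function(lens = c(chrA = 10000, chrB = 8000)) {
  genome_assembly(lens)
}

# per-bp boolean masks: one logical vector per chromosome, element i is bp
# [i-1, i) in 0-based coordinates
bp_mask <- function(gr, lens) {
  masks <- lapply(lens, function(L) logical(L))
  ch <- as.character(seqnames(gr))
  for (i in seq_along(gr)) {
    s <- start(gr)[i]; e <- end(gr)[i]
    masks[[ch[i]]][s:e] <- TRUE
  }
  masks
}

oracle_union_bp <- function(gr, lens) sum(vapply(bp_mask(gr, lens), sum, 0))

oracle_overlap_bp <- function(a, b, lens) {
  ma <- bp_mask(a, lens); mb <- bp_mask(b, lens)
  sum(vapply(names(lens), function(ch) sum(ma[[ch]] & mb[[ch]]), 0))
}

oracle_overlaps_any <- function(features, domains, lens) {
  md <- bp_mask(domains, lens)
  ch <- as.character(seqnames(features))
  vapply(seq_along(features), function(i)
    any(md[[ch[i]]][start(features)[i]:end(features)[i]]), logical(1))
}

random_intervals <- function(n, lens, max_len = 500) {
  ch <- sample(names(lens), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  s0 <- floor(runif(n) * (lens[ch] - len))
  GRanges(ch, IRanges(start = s0 + 1, width = len))
}

# naive scaled boundary distance: direct loop over every domain interval
oracle_scaled_distance <- function(mid, chrom, dom_df) {
  # dom_df: chrom, start0, end0 rows
  d <- dom_df[dom_df$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  ins <- which(mid >= d$start0 & mid < d$end0)
  if (length(ins) == 0 && any(mid == d$end0)) ins <- which(mid == d$end0)
  if (length(ins)) {
    k <- ins[1]
    w <- d$end0[k] - d$start0[k]
    dist <- min(mid - d$start0[k], d$end0[k] - mid)
    return(list(scaled = dist / w, inside = TRUE, retained = TRUE))
  }
  bdist <- ifelse(mid < d$start0, d$start0 - mid, mid - d$end0)
  k <- which.min(bdist)          # ties: first (upstream) domain
  w <- d$end0[k] - d$start0[k]
  sc <- -bdist[k] / w
  list(scaled = if (sc >= -1) sc else NA_real_, inside = FALSE,
       retained = sc >= -1)
}

# exact Mann-Whitney by enumeration of all assignments of the pooled sample
oracle_wilcox <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mu <- na * (length(b)) / 2
  p1 <- if (obs > mu) mean(us >= obs) else mean(us <= obs)
  list(U = obs, p = min(1, 2 * p1))
}

# exact two-sample KS by ECDF sweep and enumeration
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d_of <- function(x, y) max(abs(vapply(pts, function(t)
    mean(x <= t) - mean(y <= t), numeric(1))))
  obs <- d_of(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  ds <- apply(idx, 2, function(ii) d_of(pooled[ii], pooled[-ii]))
  list(D = obs, p = mean(ds >= obs - 1e-12))
}

# flat allele/nucleus tables with alleles at chosen ND values
nuclei_at <- function(nd, radius = 5, locus = "miR", expressed = NULL) {
  n <- length(nd)
  nuc <- data.frame(nucleus_id = sprintf("n%04d", seq_len(n)),
                    cell_type = "t", condition = "c",
                    center_x = 50, center_y = 50, center_z = 50,
                    radius = radius)
  r <- (1 - nd) * radius
  al <- data.frame(nucleus_id = nuc$nucleus_id, locus = locus,
                   allele_x = 50 + r, allele_y = 50, allele_z = 50)
  if (!is.null(expressed)) al$expressed <- expressed
  list(nuclei = nuc, alleles = al)
}
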