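# Observed/expected overlap enrichment against a permutation null that
# shuffles features genome-wide while preserving the multiset of feature
# lengths. The permutation loop runs on a linearized coordinate system with
# a prefix-coverage index so that no interval objects are built per
# permutation; the public GRanges surface and this fast path are checked
# against each other in the test suite.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  # restore caller RNG state when the calling function exits
  expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

# chromosome offsets mapping (chrom, 0-based pos) -> global linear coordinate
.chrom_offsets <- function(assembly) {
  sl <- as.numeric(GenomeInfoDb::seqlengths(assembly))
  nm <- GenomeInfoDb::seqnames(assembly)
  if (anyNA(sl)) stop("assembly has missing chromosome lengths")
  setNames(cumsum(c(0, sl[-length(sl)])), nm)
}

# prefix-coverage index over merged domains in linearized coordinates:
# cov(x) = covered bp in [0, x)
.domain_index <- function(domains) {
  ds <- if (inherits(domains, "domain_set")) domains else
    domain_set(domains, label = "domains")
  off <- .chrom_offsets(ds$assembly)
  gr <- sort(ds$ranges)
  s0 <- off[as.character(seqnames(gr))] + start(gr) - 1
  e0 <- off[as.character(seqnames(gr))] + end(gr)
  o <- order(s0)
  s0 <- s0[o]; e0 <- e0[o]
  b <- as.numeric(rbind(s0, e0))
  w <- e0 - s0
  cw <- as.numeric(rbind(cumsum(c(0, w[-length(w)])), cumsum(w)))
  list(b = b, cw = cw, off = off, assembly = ds$assembly)
}

.covered_before <- function(idx, x) {
  if (length(idx$b) == 0) return(numeric(length(x)))
  j <- findInterval(x, idx$b)
  out <- numeric(length(x))
  nz <- j > 0
  jj <- j[nz]
  inside <- jj %% 2 == 1
  out[nz] <- idx$cw[jj] + ifelse(inside, x[nz] - idx$b[jj], 0)
  out
}

# overlap statistic for features given as global 0-based [s0, s0+len)
.overlap_stat <- function(idx, s0, len, mode) {
  e0 <- s0 + len
  if (mode == "feature_count") {
    sum(.covered_before(idx, e0) - .covered_before(idx, s0) > 0)
  } else {
    o <- order(s0)
    s <- s0[o]; e <- e0[o]
    cme <- cummax(c(-Inf, e[-length(e)]))
    s2 <- pmin(pmax(s, cme), e)
    sum(.covered_before(idx, e) - .covered_before(idx, s2))
  }
}

# sample uniform placements over all positions where each feature fits
# within a single chromosome; returns global 0-based starts
.sample_placements <- function(lens, assembly, chrom_of = NULL) {
  sl <- as.numeric(GenomeInfoDb::seqlengths(assembly))
  nm <- GenomeInfoDb::seqnames(assembly)
  off <- .chrom_offsets(assembly)
  out <- numeric(length(lens))
  if (!is.null(chrom_of)) {  # per-chromosome shuffle keeps each chromosome
    ci <- match(chrom_of, nm)
    valid <- sl[ci] - lens + 1
    if (any(valid < 1)) stop("feature longer than its chromosome")
    return(off[ci] + floor(runif(length(lens)) * valid))
  }
  for (L in unique(lens)) {
    sel <- which(lens == L)
    valid <- pmax(0, sl - L + 1)
    if (sum(valid) == 0) stop("feature longer than every chromosome")
    ci <- sample.int(length(sl), length(sel), replace = TRUE,
                     prob = valid / sum(valid))
    out[sel] <- off[ci] + floor(runif(length(sel)) * valid[ci])
  }
  out
}

.globalize <- function(features, assembly) {
  ch <- as.character(seqnames(features))
  known <- GenomeInfoDb::seqnames(assembly)
  if (any(!ch %in% known))
    stop("feature on a chromosome absent from the assembly")
  off <- .chrom_offsets(assembly)
  list(s0 = off[ch] + start(features) - 1, len = as.numeric(width(features)),
       chrom = ch)
}

#' Expected overlap under random placement
#'
#' Analytic expectation from genome coverage fractions: in `bp` mode
#' `G * cov(features) * cov(domains)`; in `feature_count` mode
#' `n_features * cov(domains)` (features treated as points; the permutation
#' null captures the finite-width correction).
#'
#' @param features GRanges.
#' @param domains domain_set (or GRanges with lengths on its seqinfo).
#' @param mode "bp" or "feature_count".
#' @return numeric expectation in the units of `mode`.
#' @export
expected_overlap <- function(features, domains, mode = c("feature_count", "bp")) {
  mode <- match.arg(mode)
  ds <- if (inherits(domains, "domain_set")) domains else
    domain_set(domains, label = "domains")
  G <- genome_size(ds$assembly)
  if (G <= 0) stop("zero genome size")
  covd <- coverage_fraction(ds)
  if (mode == "bp") {
    covf <- sum(as.numeric(width(merge_intervals(features)))) / G
    G * covf * covd
  } else {
    length(features) * covd
  }
}

#' Shuffle features genome-wide, preserving lengths
#'
#' Each feature is relocated uniformly over every genomic position where it
#' fits within a single chromosome; the multiset of feature lengths and the
#' feature count are unchanged, and shuffled features may overlap one
#' another. With `per_chromosome = TRUE` each feature stays on its own
#' chromosome.
#'
#' @param features GRanges.
#' @param assembly Seqinfo placement universe.
#' @param seed optional integer; same seed, same output.
#' @param per_chromosome logical.
#' @return GRanges of relocated features (names preserved).
#' @export
shuffle_features <- function(features, assembly, seed = NULL,
                             per_chromosome = FALSE) {
  local_seed(seed)
  g <- .globalize(features, assembly)
  s0 <- .sample_placements(g$len, assembly,
                           chrom_of = if (per_chromosome) g$chrom else NULL)
  off <- .chrom_offsets(assembly)
  ci <- findInterval(s0, off)
  nm <- GenomeInfoDb::seqnames(assembly)
  out <- GRanges(factor(nm[ci], levels = nm),
                 IRanges(start = s0 - off[ci] + 1, width = g$len),
                 seqinfo = assembly)
  names(out) <- names(features)
  out
}

#' Permutation test for overlap enrichment
#'
#' Computes the observed overlap of `features` with `domains` (total
#' intersected bp of the feature union in `bp` mode, or the number of
#' features with >= 1 bp overlap in `feature_count` mode), the analytic
#' expectation ([expected_overlap()]), their ratio, and empirical one-sided
#' p-values from `n_perm` size-preserving shuffles
#' ([shuffle_features()]). Ties count in both tails, so
#' `p_enriched + p_depleted >= 1`. When no permutation reaches the observed
#' value the p-value is reported as the bound `"<1/n_perm"` and its numeric
#' slot floored at `1/n_perm`.
#'
#' @param features GRanges (non-empty).
#' @param domains domain_set.
#' @param mode "feature_count" or "bp".
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param per_chromosome restrict shuffles to each feature's chromosome.
#' @return an object of class `enrichment_result`.
#' @export
permutation_test <- function(features, domains,
                             mode = c("feature_count", "bp"),
                             n_perm = 1000, seed = NULL,
                             per_chromosome = FALSE) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(features) == 0) stop("empty feature set")
  ds <- if (inherits(domains, "domain_set")) domains else
    domain_set(domains, label = "domains")
  idx <- .domain_index(ds)
  g <- .globalize(features, ds$assembly)
  observed <- .overlap_stat(idx, g$s0, g$len, mode)
  expected <- expected_overlap(features, ds, mode)
  local_seed(seed)
  chrom_of <- if (per_chromosome) g$chrom else NULL
  perm <- vapply(seq_len(n_perm), function(i) {
    s0 <- .sample_placements(g$len, ds$assembly, chrom_of = chrom_of)
    .overlap_stat(idx, s0, g$len, mode)
  }, numeric(1))
  n_ge <- sum(perm >= observed)
  n_le <- sum(perm <= observed)
  fmt <- function(p) format(p, scientific = FALSE, trim = TRUE)
  p_report <-
    if (n_ge == 0 || n_le == 0) paste0("<", fmt(1 / n_perm))
    else fmt(min(n_ge, n_le) / n_perm)
  structure(list(
    observed = observed, expected = expected,
    enrichment = observed / expected,
    n_perm = n_perm,
    p_enriched = max(n_ge, 1) / n_perm,
    p_depleted = max(n_le, 1) / n_perm,
    p_report = p_report,
    mode = mode, label = ds$label, n_features = length(features),
    seed = seed, perm_mean = mean(perm)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap enrichment vs '%s' (%s mode, %d features)\n",
              x$label, x$mode, x$n_features))
  cat(sprintf("  observed %.4g, expected %.4g, enrichment %.3f\n",
              x$observed, x$expected, x$enrichment))
  cat(sprintf("  %d permutations: p_enriched %.4g, p_depleted %.4g (reported %s)\n",
              x$n_perm, x$p_enriched, x$p_depleted, x$p_report))
  invisible(x)
}
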