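# Seeded generators for every input the pipeline consumes, with known
# ground truth. Defaults emulate the study regime: a genome tiled by
# alternating cLAD/ciLAD domains with long-tailed (log-normal) sizes and
# ~40% cLAD coverage; point features planted inside cLADs with a chosen
# probability; spherical nuclei with two alleles each and a tunable
# peripheral bias of the radial position law.

#' Specification of a synthetic cLAD/ciLAD genome
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   default four 25 Mb chromosomes (a scaled-down mammalian genome).
#' @param lad_size_median median domain size in bp (log-normal median;
#'   default 500 kb, the scale of mammalian lamina-associated domains).
#' @param lad_size_sdlog log-scale dispersion of domain sizes (default 0.6,
#'   a long-tailed but not extreme size distribution).
#' @param lad_coverage target fraction of the genome covered by cLADs
#'   (default 0.40, the constitutive-LAD share of the mouse genome).
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths = setNames(rep(25e6, 4), paste0("chr", 1:4)),
                        lad_size_median = 5e5, lad_size_sdlog = 0.6,
                        lad_coverage = 0.40) {
  if (lad_coverage <= 0 || lad_coverage >= 1)
    stop("lad_coverage must lie strictly between 0 and 1")
  if (any(chrom_lengths < 1000))
    stop("chromosomes shorter than 1 kb cannot host a domain tiling")
  structure(list(chrom_lengths = chrom_lengths,
                 lad_size_median = lad_size_median,
                 lad_size_sdlog = lad_size_sdlog,
                 lad_coverage = lad_coverage),
            class = "genome_spec")
}

# interleave two size vectors and convert to an exact integer tiling of L
.tile_chromosome <- function(c_sizes, i_sizes, start_clad, L) {
  k <- length(c_sizes)
  w <- numeric(2 * k)
  if (start_clad) { w[seq(1, 2 * k, 2)] <- c_sizes; w[seq(2, 2 * k, 2)] <- i_sizes }
  else            { w[seq(1, 2 * k, 2)] <- i_sizes; w[seq(2, 2 * k, 2)] <- c_sizes }
  cum <- round(cumsum(w) / sum(w) * L)
  widths <- diff(c(0, cum))
  # rounding can zero-out a tiny domain; take the deficit from the largest
  while (any(widths < 1)) {
    i <- which.min(widths); j <- which.max(widths)
    widths[j] <- widths[j] - (1 - widths[i]); widths[i] <- 1
  }
  is_clad <- rep(c(start_clad, !start_clad), k)
  list(widths = widths, is_clad = is_clad)
}

#' Generate an alternating cLAD/ciLAD genome
#'
#' Each chromosome is tiled by alternating cLAD and ciLAD domains whose
#' sizes are log-normal draws rescaled so the realized cLAD coverage matches
#' the target (within 5%, usually exactly up to integer rounding). Pure
#' function of (spec, seed).
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @return list with `assembly` (Seqinfo), `clad` and `cilad` (domain_set).
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  local_seed(seed)
  assembly <- genome_assembly(spec$chrom_lengths, build = "synthetic")
  nm <- GenomeInfoDb::seqnames(assembly)
  sl <- GenomeInfoDb::seqlengths(assembly)
  mean_size <- spec$lad_size_median * exp(spec$lad_size_sdlog^2 / 2)
  chrs <- character(0); starts <- numeric(0); ends <- numeric(0); lab <- logical(0)
  for (ch in nm) {
    L <- as.numeric(sl[ch])
    budget_c <- spec$lad_coverage * L
    n_c <- max(1L, as.integer(round(budget_c / mean_size)))
    c_sizes <- rlnorm(n_c, log(spec$lad_size_median), spec$lad_size_sdlog)
    i_sizes <- rlnorm(n_c, log(spec$lad_size_median), spec$lad_size_sdlog)
    c_sizes <- c_sizes / sum(c_sizes) * budget_c
    i_sizes <- i_sizes / sum(i_sizes) * (L - budget_c)
    tl <- .tile_chromosome(c_sizes, i_sizes, runif(1) < 0.5, L)
    e <- cumsum(tl$widths)
    s <- c(0, e[-length(e)])
    chrs <- c(chrs, rep(ch, length(s)))
    starts <- c(starts, s); ends <- c(ends, e); lab <- c(lab, tl$is_clad)
  }
  gr <- GRanges(factor(chrs, levels = nm),
                IRanges(start = starts + 1, end = ends), seqinfo = assembly)
  clad <- domain_set(gr[lab], "cLAD", assembly)
  cilad <- domain_set(gr[!lab], "ciLAD", assembly)
  realized <- coverage_fraction(clad)
  if (abs(realized - spec$lad_coverage) > 0.05)
    stop(sprintf("unachievable coverage: realized %.3f vs target %.3f",
                 realized, spec$lad_coverage))
  list(assembly = assembly, clad = clad, cilad = cilad)
}

#' Specification of a planted feature set
#'
#' @param n_features number of features.
#' @param feature_length feature size in bp (default 100, the scale of a
#'   pre-miRNA hairpin locus).
#' @param inside_probability probability q that a feature is planted inside
#'   a cLAD (q below the cLAD coverage emulates LAD avoidance).
#' @param bias within-domain placement: "uniform", "center" or "boundary".
#' @return list of class `feature_spec`.
#' @export
feature_spec <- function(n_features = 1000, feature_length = 100,
                         inside_probability = 0.14,
                         bias = c("uniform", "center", "boundary")) {
  bias <- match.arg(bias)
  if (inside_probability < 0 || inside_probability > 1)
    stop("inside_probability must lie in [0, 1]")
  structure(list(n_features = n_features, feature_length = feature_length,
                 inside_probability = inside_probability, bias = bias),
            class = "feature_spec")
}

#' Plant features inside/outside cLAD domains
#'
#' Each feature lands fully inside a cLAD with probability
#' `inside_probability`, otherwise fully inside a ciLAD; the host domain is
#' chosen with probability proportional to the number of valid start
#' positions, and the within-domain position follows `bias`. The ground
#' truth is attached as the `planted_inside` metadata column.
#'
#' @param spec a [feature_spec()].
#' @param genome output of [generate_genome()] (or a list with `clad` and
#'   `cilad` domain_sets).
#' @param seed integer seed.
#' @return GRanges with `planted_inside` metadata.
#' @export
place_features <- function(spec, genome, seed) {
  stopifnot(inherits(spec, "feature_spec"))
  local_seed(seed)
  Lf <- spec$feature_length
  place_in <- function(dom, n) {
    gr <- dom$ranges
    w <- width(gr)
    ok <- which(w >= Lf)
    if (length(ok) == 0) stop("no domain can host a feature of length ", Lf)
    valid <- w[ok] - Lf + 1
    pick <- ok[sample.int(length(ok), n, replace = TRUE, prob = valid / sum(valid))]
    s0 <- start(gr)[pick] - 1
    w0 <- width(gr)[pick]
    offs <- switch(spec$bias,
      uniform = floor(runif(n) * (w0 - Lf + 1)),
      center = floor((w0 - Lf) / 2),
      boundary = ifelse(runif(n) < 0.5, 0, w0 - Lf))
    GRanges(seqnames(gr)[pick], IRanges(start = s0 + offs + 1, width = Lf),
            seqinfo = dom$assembly)
  }
  inside <- runif(spec$n_features) < spec$inside_probability
  parts <- list()
  if (any(inside)) parts$inn <- place_in(genome$clad, sum(inside))
  if (any(!inside)) parts$out <- place_in(genome$cilad, sum(!inside))
  out <- GRanges(seqinfo = genome$clad$assembly)
  ord <- integer(0)
  if (!is.null(parts$inn)) { out <- c(out, parts$inn); ord <- c(ord, which(inside)) }
  if (!is.null(parts$out)) { out <- c(out, parts$out); ord <- c(ord, which(!inside)) }
  out <- out[order(ord)]
  names(out) <- paste0("feature_", seq_along(out))
  mcols(out)$planted_inside <- inside
  out
}

#' Specification of a synthetic nucleus population
#'
#' @param n_nuclei number of nuclei (each with two alleles per locus).
#' @param radius_mean,radius_sd nuclear radius distribution in micrometres
#'   (default 4 +/- 0.4, a typical murine lymphocyte nucleus).
#' @param radial_bias beta of the allele radial law: density proportional to
#'   `r^2 * exp(beta * r / R)` on \[0, R\]. beta = 0 is uniform in the
#'   sphere; large beta concentrates alleles at the periphery.
#' @param expression_probability per-allele independent probability of a
#'   nascent-transcription signal (default 0.2, yielding mostly monoallelic
#'   calls among expressing cells).
#' @param lamina_shell_fraction fraction of the radius defining ground-truth
#'   lamina contact (default 0.05).
#' @param locus,cell_type,condition labels carried into the tables.
#' @return list of class `nucleus_spec`.
#' @export
nucleus_spec <- function(n_nuclei = 500, radius_mean = 4, radius_sd = 0.4,
                         radial_bias = 0, expression_probability = 0.2,
                         lamina_shell_fraction = 0.05, locus = "miR",
                         cell_type = "synthetic", condition = "none") {
  stopifnot(n_nuclei >= 1, radius_mean > 0)
  structure(list(n_nuclei = n_nuclei, radius_mean = radius_mean,
                 radius_sd = radius_sd, radial_bias = radial_bias,
                 expression_probability = expression_probability,
                 lamina_shell_fraction = lamina_shell_fraction,
                 locus = locus, cell_type = cell_type, condition = condition),
            class = "nucleus_spec")
}

# draw relative radii t = r/R from density ~ t^2 exp(beta t) on [0,1]
.sample_relative_radius <- function(n, beta) {
  if (beta == 0) return(runif(n)^(1 / 3))   # uniform in the sphere
  grid <- seq(0, 1, length.out = 4001)
  pdf <- grid^2 * exp(beta * grid)
  cdf <- cumsum(pdf); cdf <- cdf / cdf[length(cdf)]
  inv <- approxfun(cdf, grid, yleft = 0, yright = 1, ties = "ordered")
  inv(runif(n))
}

#' Generate a synthetic nucleus population with two alleles each
#'
#' Allele radial positions follow density `r^2 exp(beta r / R)` on
#' \[0, R\] (beta = 0 reduces to uniform-in-sphere, which has the closed
#' form P(nd <= x) = 1 - (1 - x)^3); directions are isotropic. Expression
#' flags are independent Bernoulli draws and lamina-contact ground truth
#' follows the shell fraction. Pure function of (spec, seed).
#'
#' @param spec a [nucleus_spec()].
#' @param seed integer seed.
#' @return list with `nuclei` and `alleles` data.frames; alleles carry the
#'   ground-truth `true_nd` and `lamina_contact` columns.
#' @export
generate_nuclei <- function(spec, seed) {
  stopifnot(inherits(spec, "nucleus_spec"))
  local_seed(seed)
  n <- spec$n_nuclei
  R <- pmax(rnorm(n, spec$radius_mean, spec$radius_sd), spec$radius_mean / 4)
  cen <- matrix(runif(3 * n, 0, 100), ncol = 3)
  nuclei <- data.frame(nucleus_id = sprintf("nuc_%06d", seq_len(n)),
                       cell_type = spec$cell_type, condition = spec$condition,
                       center_x = cen[, 1], center_y = cen[, 2],
                       center_z = cen[, 3], radius = R,
                       stringsAsFactors = FALSE)
  m <- 2L * n
  idx <- rep(seq_len(n), each = 2L)
  t_rel <- .sample_relative_radius(m, spec$radial_bias)
  dir <- matrix(rnorm(3 * m), ncol = 3)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  dir <- dir / nrm
  pos <- cen[idx, , drop = FALSE] + dir * (t_rel * R[idx])
  nd <- 1 - t_rel
  alleles <- data.frame(nucleus_id = nuclei$nucleus_id[idx],
                        locus = spec$locus,
                        allele_x = pos[, 1], allele_y = pos[, 2],
                        allele_z = pos[, 3],
                        expressed = runif(m) < spec$expression_probability,
                        lamina_contact = nd <= spec$lamina_shell_fraction,
                        true_nd = nd,
                        stringsAsFactors = FALSE)
  list(nuclei = nuclei, alleles = alleles)
}
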