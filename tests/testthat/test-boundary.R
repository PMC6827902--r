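# Scaled distance to domain boundaries and the rank-sum comparison.

# single 100 kb domain at [100000, 200000) on a 1 Mb chromosome
single_domain <- function() {
  asm <- genome_assembly(c(chr1 = 1e6))
  domain_set(GRanges("chr1", IRanges(100001, 200000)), "cLAD", asm)
}

feature_at <- function(mid0, asm = genome_assembly(c(chr1 = 1e6))) {
  # width-2 feature whose midpoint is exactly mid0 (0-based)
  GRanges("chr1", IRanges(mid0, mid0 + 1), seqinfo = asm)   # [mid0-1, mid0+1)
}

test_that("sign convention and filter on a single domain", {
  ds <- single_domain()
  # midpoint at the domain center
  expect_equal(scaled_distance(feature_at(150000), ds)$scaled, 0.5)
  # midpoint exactly on the start boundary
  expect_equal(scaled_distance(feature_at(100000), ds)$scaled, 0.0)
  # and on the end boundary (classified inside with distance 0)
  expect_equal(scaled_distance(feature_at(200000), ds)$scaled, 0.0)
  # one full domain size outside: retained at exactly -1
  r <- scaled_distance(feature_at(300000), ds)
  expect_equal(r$scaled, -1.0)
  expect_true(r$retained)
  expect_false(r$inside)
  # 1.5 domain sizes outside: discarded, tagged not errored
  r <- scaled_distance(feature_at(350000), ds)
  expect_false(r$retained)
  expect_equal(r$reason, "beyond_one_domain_size")
  # upstream side is symmetric
  expect_equal(scaled_distance(feature_at(50000), ds)$scaled, -0.5)
})

test_that("feature on a chromosome without domains is discarded with a reason", {
  asm <- genome_assembly(c(chr1 = 1e6, chr2 = 1e6))
  ds <- domain_set(GRanges("chr1", IRanges(100001, 200000)), "cLAD", asm)
  f <- GRanges("chr2", IRanges(500000, 500001), seqinfo = asm)
  r <- scaled_distance(f, ds)
  expect_false(r$retained)
  expect_equal(r$reason, "no_domain_on_chromosome")
})

test_that("closest domain minimizes boundary distance; nearer domain scales", {
  asm <- genome_assembly(c(chr1 = 1e6))
  # 10 kb domain at [0, 10000), 100 kb domain at [50000, 150000)
  ds <- domain_set(GRanges("chr1", IRanges(c(1, 50001), c(10000, 150000))),
                   "cLAD", asm)
  r <- scaled_distance(feature_at(15000), ds)    # 5 kb right of small domain
  expect_equal(r$scaled, -5000 / 10000)
  r <- scaled_distance(feature_at(45000), ds)    # 5 kb left of large domain
  expect_equal(r$scaled, -5000 / 100000)
})

test_that("scaled distances are translation and scale invariant", {
  set.seed(77)
  gen <- generate_genome(genome_spec(chrom_lengths = c(chr1 = 2e6),
                                     lad_size_median = 1e5), seed = 3)
  f <- shuffle_features(GRanges("chr1", IRanges(1, width = rep(2, 300))),
                        gen$assembly, seed = 4)
  base <- scaled_distance(f, gen$clad)

  shift <- 12345
  asm2 <- genome_assembly(c(chr1 = 2e6 + shift))
  shift_gr <- function(g) GRanges(seqnames(g), IRanges(start(g) + shift,
                                                       end(g) + shift))
  ds2 <- domain_set(shift_gr(gen$clad$ranges), "cLAD", asm2)
  f2 <- shift_gr(f)
  expect_equal(scaled_distance(f2, ds2)$scaled, base$scaled)

  k <- 7
  asm3 <- genome_assembly(c(chr1 = 2e6 * k))
  scale_gr <- function(g) GRanges(seqnames(g),
                                  IRanges((start(g) - 1) * k + 1, end(g) * k))
  ds3 <- domain_set(scale_gr(gen$clad$ranges), "cLAD", asm3)
  f3 <- scale_gr(f)
  expect_equal(scaled_distance(f3, ds3)$scaled, base$scaled, tolerance = 1e-9)
})

test_that("implementation agrees with a naive per-feature oracle", {
  set.seed(55)
  for (rep in 1:10) {
    gen <- generate_genome(genome_spec(chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
                                       lad_size_median = 8e4,
                                       lad_coverage = runif(1, 0.25, 0.6)),
                           seed = 500 + rep)
    f <- shuffle_features(GRanges("chr1", IRanges(1, width = rep(2, 100))),
                          gen$assembly, seed = 600 + rep)
    got <- scaled_distance(f, gen$clad)
    gr <- gen$clad$ranges
    dom_df <- data.frame(chrom = as.character(seqnames(gr)),
                         start0 = start(gr) - 1, end0 = end(gr))
    for (i in seq_along(f)) {
      mid <- (start(f)[i] - 1 + end(f)[i]) / 2
      exp_i <- oracle_scaled_distance(mid, as.character(seqnames(f)[i]), dom_df)
      expect_equal(got$retained[i], exp_i$retained)
      if (exp_i$retained) expect_equal(got$scaled[i], exp_i$scaled)
    }
  }
})

test_that("retained values stay in [-1, 0.5]; center planting collapses to 0.5", {
  gen <- generate_genome(genome_spec(), seed = 41)
  f <- shuffle_features(GRanges("chr1", IRanges(1, width = rep(2, 2000))),
                        gen$assembly, seed = 42)
  r <- scaled_distance(f, gen$clad)
  expect_true(all(r$scaled[r$retained] >= -1 & r$scaled[r$retained] <= 0.5))
  expect_true(all(r$inside[r$retained] == (r$scaled[r$retained] >= 0)))

  fc <- place_features(feature_spec(n_features = 200, inside_probability = 1,
                                    bias = "center"), gen, seed = 43)
  rc <- scaled_distance(fc, gen$clad)
  expect_true(all(abs(rc$scaled - 0.5) < 1e-4))  # half-bp midpoint rounding
})

test_that("uniform placement matches the closed-form null distribution", {
  gen <- generate_genome(genome_spec(chrom_lengths = c(chr1 = 1e7),
                                     lad_size_median = 3e5), seed = 61)
  f <- shuffle_features(GRanges("chr1", IRanges(1, width = rep(1, 5000))),
                        gen$assembly, seed = 62)
  r <- scaled_distance(f, gen$clad)
  vals <- r$scaled[r$retained]
  null <- scaled_distance_null_cdf(gen$clad)
  D <- suppressWarnings(ks.test(vals, null$cdf)$statistic)
  expect_lt(unname(D), 0.05)
  expect_lt(abs(mean(r$retained) - null$retained_fraction), 0.03)
})

test_that("rank-sum comparison: maximal separation and exact enumeration", {
  a <- c(0.4, 0.45, 0.5); b <- c(-0.9, -0.8, -0.7)
  res <- compare_distance_distributions(a, b)
  expect_equal(res$statistic, 9)                 # all 9 pairs separate
  orc <- oracle_wilcox(a, b)
  expect_equal(res$statistic, orc$U)
  expect_equal(res$p.value, orc$p)

  expect_error(compare_distance_distributions(numeric(0), b), "non-empty")
  # identical groups: no separation up to the continuity correction
  set.seed(9); x <- runif(30)
  expect_gt(compare_distance_distributions(x, x)$p.value, 0.9)
})

test_that("rank-sum test holds its type-I error under the null", {
  set.seed(131)
  p <- replicate(1000, compare_distance_distributions(runif(25), runif(25))$p.value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
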