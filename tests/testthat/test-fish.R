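# Radial FISH statistics: ND, shells, KS, colocalization, allelic calls.

test_that("nd maps center to 1, surface to 0, half radius to 0.5", {
  nuc <- data.frame(nucleus_id = "n1", center_x = 10, center_y = 20,
                    center_z = 30, radius = 5)
  al <- data.frame(nucleus_id = "n1",
                   allele_x = c(10, 15, 12.5), allele_y = 20, allele_z = 30)
  nd <- normalized_distance(al, nuc)
  expect_equal(nd$nd, c(1, 0, 0.5))
  expect_equal(nd$shell, c(9L, 0L, 5L))
})

test_that("alleles slightly outside clamp to the periphery; farther error", {
  nuc <- data.frame(nucleus_id = "n1", center_x = 0, center_y = 0,
                    center_z = 0, radius = 5)
  near <- data.frame(nucleus_id = "n1", allele_x = 5.05, allele_y = 0,
                     allele_z = 0)
  expect_equal(normalized_distance(near, nuc)$nd, 0)
  far <- data.frame(nucleus_id = "n1", allele_x = 5.5, allele_y = 0,
                    allele_z = 0)
  expect_error(normalized_distance(far, nuc), "outside the nuclear sphere")
  orphan <- data.frame(nucleus_id = "nX", allele_x = 0, allele_y = 0,
                       allele_z = 0)
  expect_error(normalized_distance(orphan, nuc), "unknown nucleus")
})

test_that("nd is invariant under rigid motion of nucleus plus alleles", {
  set.seed(8)
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 50), seed = 8)
  base <- normalized_distance(pop$alleles, pop$nuclei)$nd
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(df, cols, shift) {
    m <- as.matrix(df[, cols]) %*% Rz
    df[, cols] <- sweep(m, 2, shift, "+")
    df
  }
  nuc2 <- rot(pop$nuclei, c("center_x", "center_y", "center_z"), c(3, -4, 5))
  al2 <- rot(pop$alleles, c("allele_x", "allele_y", "allele_z"), c(3, -4, 5))
  expect_equal(normalized_distance(al2, nuc2)$nd, base, tolerance = 1e-9)
})

test_that("shell histogram counts conserve alleles and close the last bin", {
  h <- shell_histogram(seq(0.05, 0.95, by = 0.1))  # one allele per bin midpoint
  expect_equal(h$counts, rep(1L, 10))
  expect_equal(sum(h$fractions), 1)
  h <- shell_histogram(rep(1.0, 7))                # nd = 1 belongs to shell 9
  expect_equal(h$counts[10], 7L)
  expect_error(shell_histogram(numeric(0)), "empty")
  expect_error(shell_of(1.2), "0, 1")
})

test_that("uniform-in-sphere placement follows 1 - (1-x)^3", {
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 20000, radial_bias = 0),
                         seed = 14)
  nd <- normalized_distance(pop$alleles, pop$nuclei)$nd
  expect_lt(abs(mean(nd <= 0.1) - (1 - 0.9^3)), 0.015)
})

test_that("ks_compare handles degenerate and hand-computed cases", {
  expect_equal(ks_compare(c(.1, .2, .3, .4), c(.1, .2, .3, .4))$D, 0)
  expect_equal(ks_compare(c(.1, .15, .2), c(.5, .6, .7))$D, 1)
  expect_equal(ks_compare(c(.1, .2, .3), c(.2, .3, .4))$D, 1 / 3)
  expect_error(ks_compare(0.5, c(.1, .2)), "size >= 2")
})

test_that("lamina colocalization: geometry rule and imaging flags", {
  nuc <- data.frame(nucleus_id = c("a", "b"), center_x = 0, center_y = 0,
                    center_z = 0, radius = 5)
  on_surface <- data.frame(nucleus_id = c("a", "a", "b", "b"),
                           allele_x = c(5, -5, 5, -5), allele_y = 0,
                           allele_z = 0)
  expect_equal(lamina_colocalization(on_surface, nuc, 0.1)$frac_cells, 1.0)
  at_center <- data.frame(nucleus_id = c("a", "a", "b", "b"),
                          allele_x = 0, allele_y = 0, allele_z = 0)
  expect_equal(lamina_colocalization(at_center, nuc, 4.9)$frac_alleles, 0.0)
  # verbatim imaging flags override geometry
  at_center$lamina_contact <- c(TRUE, FALSE, FALSE, FALSE)
  cc <- lamina_colocalization(at_center, nuc, 0.1)
  expect_equal(cc$frac_alleles, 0.25)
  expect_equal(cc$frac_cells, 0.5)
})

test_that("generator lamina ground truth is recovered by the fraction rule", {
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 2000, radial_bias = 5,
                                      lamina_shell_fraction = 0.05), seed = 19)
  truth_cells <- mean(tapply(pop$alleles$lamina_contact,
                             pop$alleles$nucleus_id, any))
  al <- pop$alleles[, setdiff(names(pop$alleles), "lamina_contact")]
  cc <- lamina_colocalization(al, pop$nuclei, shell_thickness = 0.05,
                              unit = "fraction")
  expect_equal(cc$frac_cells, truth_cells)
})

test_that("allelic summary classifies cells and validates ploidy", {
  al <- data.frame(
    nucleus_id = rep(sprintf("c%02d", 1:10), each = 2), locus = "miR",
    allele_x = 0, allele_y = 0, allele_z = 0,
    expressed = c(rep(c(TRUE, FALSE), 6),          # 6 monoallelic cells
                  rep(TRUE, 4),                    # 2 biallelic
                  rep(FALSE, 4)))                  # 2 silent
  s <- allelic_summary(al)
  expect_equal(s$n_mono, 6); expect_equal(s$n_bi, 2); expect_equal(s$n_silent, 2)
  expect_equal(s$frac_mono_expressing, 0.75)
  expect_equal(s$frac_mono_all, 0.6)

  silent <- within(al, expressed <- FALSE)
  s <- allelic_summary(silent)
  expect_equal(c(s$n_mono, s$n_bi), c(0, 0))
  expect_equal(s$frac_silent_all, 1)

  tri <- rbind(al, data.frame(nucleus_id = "c01", locus = "miR", allele_x = 0,
                              allele_y = 0, allele_z = 0, expressed = TRUE))
  expect_error(allelic_summary(tri), "more than 2 alleles")
})

test_that("independent per-allele expression gives bi/(mono+bi) = p/(2-p)", {
  p <- 0.2
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 5000,
                                      expression_probability = p), seed = 27)
  s <- allelic_summary(pop$alleles)
  expect_lt(abs(s$frac_bi_expressing - p / (2 - p)),
            3 * sqrt(0.111 * 0.889 / (s$n_mono + s$n_bi)))
})

test_that("expressed vs silent ND comparison", {
  nd <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  df <- data.frame(nd = rep(nd, 2), expressed = rep(c(TRUE, FALSE), each = 5))
  r <- expressed_vs_silent_nd(df)
  expect_equal(r$ks$D, 0)                      # identical groups

  # expression restricted to the nuclear interior forces D >= 0.5
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 300), seed = 33)
  nds <- normalized_distance(pop$alleles, pop$nuclei)
  nds$expressed <- nds$nd > 0.5
  if (any(nds$expressed) && any(!nds$expressed))
    expect_gte(expressed_vs_silent_nd(nds)$ks$D, 0.5)

  expect_error(expressed_vs_silent_nd(data.frame(nd = 1, expressed = TRUE)),
               "non-empty")
})

test_that("position-independent expression yields mostly null KS calls", {
  hits <- 0
  for (i in 1:100) {
    pop <- generate_nuclei(nucleus_spec(n_nuclei = 150, radial_bias = 3),
                           seed = 1000 + i)
    nds <- normalized_distance(pop$alleles, pop$nuclei)
    if (sum(nds$expressed) < 2 || sum(!nds$expressed) < 2) next
    r <- expressed_vs_silent_nd(nds)
    if (r$ks$p.value < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 6)   # >= 94% non-significant at alpha = 0.05
})

test_that("allele tables round-trip through the flat TSV format", {
  pop <- generate_nuclei(nucleus_spec(n_nuclei = 30), seed = 44)
  f <- tempfile(fileext = ".tsv")
  write_allele_table(pop$nuclei, pop$alleles, f)
  back <- read_allele_table(f)
  expect_equal(nrow(back$nuclei), 30)
  expect_equal(nrow(back$alleles), 60)
  nd1 <- normalized_distance(pop$alleles, pop$nuclei)$nd
  nd2 <- normalized_distance(back$alleles, back$nuclei)$nd
  expect_equal(nd2, nd1, tolerance = 1e-6)
  expect_equal(back$alleles$expressed, pop$alleles$expressed)
})
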