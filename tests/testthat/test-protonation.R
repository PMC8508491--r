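test_that("pattern counting is exact binomial arithmetic", {
  expect_identical(pattern_count(20, 7), 77520)
  expect_identical(pattern_count(4, 2), 6)
  expect_identical(pattern_count(13, 13), 1)
  expect_identical(pattern_count(5, 0), 1)
  expect_error(pattern_count(4, 5), "exceed")
  expect_error(pattern_count(4, -1), "non-negative")
  # exactness on a larger case against Pascal recurrence
  expect_identical(pattern_count(40, 20), pattern_count(39, 19) + pattern_count(39, 20))
})

test_that("random patterns carry exactly k protons and are uniform", {
  expect_identical(random_pattern(5, 0), "00000")
  expect_identical(random_pattern(3, 3), "111")
  set.seed(99)
  for (i in 1:50) {
    b <- random_pattern(12, 5)
    expect_equal(nchar(b), 12L)
    expect_equal(sum(strsplit(b, "")[[1]] == "1"), 5L)
  }
  # chi-square against exhaustive enumeration of C(6,3) = 20 patterns
  set.seed(123)
  draws <- replicate(4000, random_pattern(6, 3))
  counts <- table(factor(draws, levels = enumerate_patterns(collinear_sites(6), 3)$bits))
  expect_equal(length(counts), 20L)
  chisq <- sum((counts - 200)^2 / 200)
  expect_lt(chisq, qchisq(0.999, df = 19))
})

test_that("Coulomb energy follows the pairwise 1/r law", {
  two <- site_table(1:2, c("K", "K"), c(0, 10), c(0, 0), c(0, 0))
  expect_equal(coulomb_energy("10", two), 0)            # one occupied site
  expect_equal(coulomb_energy("11", two), 138.935, tolerance = 1e-9)
  expect_equal(coulomb_energy("11", two, relative_permittivity = 2),
               138.935 / 2, tolerance = 1e-9)

  # scale invariance: E(lambda * coords) = E(coords) / lambda
  s <- tiny_sites()
  lam <- 2.5
  s2 <- site_table(s$index, s$residue_type, s$x * lam, s$y * lam, s$z * lam)
  expect_equal(coulomb_energy("110110", s2),
               coulomb_energy("110110", s) / lam, tolerance = 1e-10)

  # additivity over clusters at (effectively) infinite separation
  far <- site_table(1:4, rep("K", 4), c(0, 3, 1e8, 1e8 + 3), rep(0, 4), rep(0, 4))
  near <- site_table(1:2, rep("K", 2), c(0, 3), c(0, 0), c(0, 0))
  expect_equal(coulomb_energy("1111", far), 2 * coulomb_energy("11", near),
               tolerance = 1e-4)

  co <- site_table(1:2, rep("K", 2), c(1, 1), c(1, 1), c(1, 1))
  expect_error(coulomb_energy("11", co), "singularity|coincident")
})

test_that("arginine counting respects site types", {
  s <- tiny_sites()  # types R K K H R N-terminus
  expect_equal(arg_count("100010", s), 2L)
  expect_equal(arg_count("011101", s), 0L)
})

test_that("Monte-Carlo minimization handles forced and toy systems", {
  s <- tiny_sites()
  res0 <- monte_carlo_minimize(s, 0, steps = 10, seed = 1)
  expect_equal(res0$bits, "000000")
  expect_equal(res0$energy, 0)

  # 8 collinear equidistant sites, k = 2: maximal separation wins
  lin <- collinear_sites(8)
  res <- monte_carlo_minimize(lin, 2, steps = 2000, seed = 4)
  expect_equal(res$bits[1], "10000001")
})

test_that("Monte-Carlo minimum matches exhaustive enumeration and is reproducible", {
  sites <- generate_site_geometry(n_sites = 12, residue_mix = c(R = 3, K = 6, H = 2, "N-terminus" = 1),
                                  seed = 8)
  enum <- enumerate_patterns(sites, 5)          # C(12,5) = 792, brute force
  mc <- monte_carlo_minimize(sites, 5, steps = 5000, seed = 21)
  expect_equal(mc$bits[1], enum$bits[1])
  expect_equal(mc$energy[1], enum$energy[1], tolerance = 1e-10)
  expect_false(is.unsorted(mc$energy))
  # every recorded pattern keeps the charge invariant
  expect_true(all(vapply(mc$bits, function(b)
    sum(strsplit(b, "")[[1]] == "1"), 0L) == 5L))
  # bit-reproducibility under the same seed
  mc2 <- monte_carlo_minimize(sites, 5, steps = 5000, seed = 21)
  expect_identical(mc, mc2)
})

test_that("MMSA selection keeps arginine-rich low-energy patterns stably", {
  s <- tiny_sites()
  # all arg_counts equal -> lowest-energy n_select returned unchanged
  pool <- data.frame(bits = c("011000", "011010", "010011"),
                     energy = c(1, 2, 3), arg_count = c(0L, 0L, 0L))
  expect_equal(mmsa_select(pool, n_lowest = 3, n_select = 2)$bits, pool$bits[1:2])

  pool2 <- data.frame(bits = c("010010", "100001", "100010"),
                      energy = c(1, 2, 3), arg_count = c(0L, 2L, 1L))
  sel <- mmsa_select(pool2, n_lowest = 3, n_select = 2)
  expect_equal(sel$arg_count, c(2L, 1L))
  expect_equal(sel$rank, 1:2)

  expect_error(mmsa_select(pool2, n_select = 5), "insufficient")
})

test_that("MMSA matches an independent sort oracle on a constructed pool", {
  set.seed(31)
  n <- 10
  bits <- replicate(120, random_pattern(n, 4))
  bits <- unique(bits)
  pool <- data.frame(bits = bits,
                     energy = sort(runif(length(bits), 100, 900)),
                     arg_count = sample(0:3, length(bits), replace = TRUE))
  sel <- mmsa_select(pool, n_lowest = 100, n_select = 10)
  # oracle: sort the same 100-pattern pool by (-arg_count, energy)
  oracle <- head(pool, 100)
  oracle <- oracle[order(-oracle$arg_count, oracle$energy), ]
  expect_equal(sel$bits, head(oracle$bits, 10))

  # duplicates beyond the first occurrence are ignored
  dup <- rbind(pool[1, ], pool)
  dup <- dup[order(dup$energy), ]
  sel2 <- mmsa_select(dup, n_lowest = 100, n_select = 10)
  expect_equal(sel2$bits, sel$bits)
})
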