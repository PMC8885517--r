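# Envelope engine vs the exact enumeration oracle, and envelope properties.

test_that("single-atom and two-atom envelopes match hand-computed values", {
  # one carbon: natural 12C/13C split
  c1 <- elemental_composition(c(C = 1L, H = 0L, N = 0L, O = 0L, S = 0L))
  env <- brute_force_envelope(c1)
  expect_equal(env$abundance, c(0.9893, 0.0107), tolerance = 1e-12)
  # O2: three-term self-convolution of oxygen's isotope vector
  o2 <- elemental_composition(c(C = 0L, H = 0L, N = 0L, O = 2L, S = 0L))
  a <- c(0.99757, 0.00038, 0.00205)
  expected <- c(a[1]^2, 2 * a[1] * a[2], 2 * a[1] * a[3] + a[2]^2,
                2 * a[2] * a[3], a[3]^2)
  expect_equal(envelope(o2)$abundance, expected / sum(expected),
               tolerance = 1e-9)
  # two labeled nitrogens at p = 0.97: binomial by hand at offsets -2,-1,0
  n2 <- elemental_composition(c(C = 0L, H = 0L, N = 2L, O = 0L, S = 0L),
                              n_labeled_N = 2L)
  env <- brute_force_envelope(n2, p = 0.97)
  expect_equal(env$offset, c(-2L, -1L, 0L))
  expect_equal(env$abundance, c(0.03^2, 2 * 0.97 * 0.03, 0.97^2),
               tolerance = 1e-12)
})

test_that("convolution envelope agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:50) {
    comp <- random_small_comp()
    p <- runif(1, 0.9, 1)
    a <- envelope(comp, p)
    b <- brute_force_envelope(comp, p)
    common <- intersect(a$offset, b$offset)
    expect_true(length(common) >= 1)
    expect_lt(max(abs(a$abundance[match(common, a$offset)] -
                      b$abundance[match(common, b$offset)])), 1e-9)
    # centroid masses agree too
    expect_lt(max(abs(a$mz[match(common, a$offset)] -
                      b$mz[match(common, b$offset)])), 1e-9)
  }
})

test_that("every envelope is unit-normalized with increasing offsets and ~1/z spacing", {
  set.seed(21)
  for (i in 1:200) {
    comp <- random_peptide_comp(sample(c("light", "heavy"), 1))
    env <- envelope(comp, runif(1, 0.9, 1))
    expect_equal(sum(env$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(env$offset) == 1L))
    z <- max(1, comp$charge)
    sp <- diff(env$mz)
    expect_true(all(sp > 0.99 / z & sp < 1.01 / z))
  }
})

test_that("complete labeling leaves no satellite peaks", {
  comp <- build_composition(fig2_ion("heavy"))
  env <- envelope(comp, 1.0)
  expect_true(all(env$offset >= 0))
  expect_equal(m1_over_m(comp, 1.0), 0)
})

test_that("heavy envelope at natural 15N abundance equals the light envelope", {
  seqs <- c("GASK", "LTYYTPEYETK")
  for (s in seqs) {
    h <- build_composition(peptide_ion(s, "", 2, "heavy"))
    l <- build_composition(peptide_ion(s, "", 2, "light"))
    eh <- envelope(h, 0.003640)
    el <- envelope(l)
    # compare on the light offset frame: heavy offsets are anchored at the
    # all-15N species, n_labeled_N above the light monoisotopic peak
    shift <- h$n_labeled_N
    common <- intersect(eh$offset + shift, el$offset)
    expect_lt(max(abs(eh$abundance[match(common, eh$offset + shift)] -
                      el$abundance[match(common, el$offset)])), 1e-9)
  }
})

test_that("centroid m/z at offset 0 equals the monoisotopic m/z for clean anchors", {
  set.seed(31)
  for (i in 1:10) {
    comp <- random_peptide_comp("light")
    env <- envelope(comp)  # light: no negative offsets, offset 0 is pure
    expect_equal(env$mz[env$offset == 0], mono_mz(comp), tolerance = 1e-6)
    h <- random_peptide_comp("heavy")
    envh <- envelope(h, 1.0)  # fully labeled: offset 0 is the all-15N species
    expect_equal(envh$mz[envh$offset == 0], mono_mz(h), tolerance = 1e-6)
  }
})

test_that("fraction_in_mono is the offset-0 abundance and rises with p", {
  comp <- build_composition(fig2_ion("heavy"))
  env <- envelope(comp, 0.97)
  expect_equal(fraction_in_mono(comp, 0.97),
               env$abundance[env$offset == 0])
  # oracle check at enumerable size
  small <- elemental_composition(c(C = 2L, H = 3L, N = 3L, O = 1L, S = 0L),
                                 n_labeled_N = 3L)
  bf <- brute_force_envelope(small, 0.95)
  expect_equal(fraction_in_mono(small, 0.95),
               bf$abundance[bf$offset == 0], tolerance = 1e-9)
  grid <- seq(0.9, 1.0, by = 0.01)
  f <- vapply(grid, function(p) fraction_in_mono(comp, p), numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("M-1/M is strictly decreasing in p and ordered across peptides by N count", {
  set.seed(41)
  grid <- c(0.90, 0.92, 0.95, 0.97, 0.99, 0.995, 0.999)
  for (i in 1:5) {
    comp <- random_peptide_comp("heavy")
    r <- vapply(grid, function(p) m1_over_m(comp, p), numeric(1))
    expect_true(all(diff(r) < 0))
  }
  # more labeled nitrogens -> larger satellite at fixed p
  few <- build_composition(peptide_ion("GAGAGAGAK", "", 1, "heavy"))   # 9 N
  many <- build_composition(peptide_ion("RHRHRHRHR", "", 1, "heavy"))  # 19+ N
  expect_gt(m1_over_m(many, 0.97), m1_over_m(few, 0.97))
})

test_that("degenerate and invalid envelope inputs error", {
  comp <- build_composition(fig2_ion("heavy"))
  expect_error(envelope(comp, -0.1), "\\[0, 1\\]")
  expect_error(envelope(comp, 1.2), "\\[0, 1\\]")
  expect_error(m1_over_m(build_composition(fig2_ion("light")), 0.97), "heavy")
  big <- build_composition(peptide_ion("LTYYTPEYETK", "", 1, "heavy"))
  expect_error(brute_force_envelope(big, 0.97), "enumeration bound")
})

test_that("max normalization reports the largest peak as 100", {
  env <- envelope(build_composition(fig2_ion("heavy")), 0.95, normalize = "max")
  expect_equal(max(env$abundance), 100)
})
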