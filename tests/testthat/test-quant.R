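# Pair quantification: efficiency correction, CS scoring, sentinels and
# symmetry properties.

test_that("corrected_abundance scales by the monoisotopic fraction", {
  expect_equal(corrected_abundance(100, 1), 100)
  expect_equal(corrected_abundance(100, 0.5), 200)
  expect_error(corrected_abundance(100, 0), "\\(0, 1\\]")
})

test_that("cs_score identities: perfect match, orthogonality, scale invariance", {
  theo <- envelope(build_composition(fig2_ion("heavy")), 0.97)
  v <- theo$abundance[match(0:2, theo$offset)]
  expect_equal(cs_score(v, v), 1.0)
  expect_equal(cs_score(5 * v, v), 1.0)
  expect_equal(cs_score(c(1, 0, 0), c(0, 1, 0)), 0.0)
  expect_true(is.na(cs_score(c(0, 0, 0), v)))  # no signal: undefined, not 0
  expect_error(cs_score(c(1, 2), v), "length 3")
})

test_that("a simulated 2:1 pair is recovered and the correction is necessary", {
  cfg <- sim_config(n_proteins = 3, peptides_per_protein = 3, ratios = 2,
                    p = 0.95, noise_cv = 0, rt_range = c(60, 200), seed = 14)
  sim <- simulate_scans(cfg)
  config <- run_config(p = 0.95)
  q <- quantify_experiment(sim$ids, sim$scans, config)
  expect_equal(q$ratio, rep(2, nrow(q)), tolerance = 1e-3)
  # uncorrected monoisotopic ratio is biased high: the heavy channel loses
  # abundance into M-1, M-2 satellites that the light channel does not
  raw <- q$light_mono / q$heavy_mono
  expect_true(all(raw > 2.1))
  expect_true(all(q$f_heavy < q$f_light))
})

test_that("area mode recovers the same ratios as intensity mode", {
  cfg <- sim_config(n_proteins = 2, peptides_per_protein = 2, ratios = 0.5,
                    p = 0.97, noise_cv = 0, rt_range = c(60, 150), seed = 15)
  sim <- simulate_scans(cfg)
  qa <- quantify_experiment(sim$ids, sim$scans,
                            run_config(p = 0.97, mode = "area"))
  expect_equal(qa$ratio, rep(0.5, nrow(qa)), tolerance = 0.01)
})

test_that("one-sided pairs keep sentinel ratios instead of being dropped", {
  cfg <- sim_config(n_proteins = 4, peptides_per_protein = 2, ratios = 1,
                    p = 0.97, n_missing_heavy = 2, rt_range = c(60, 200),
                    seed = 16)
  sim <- simulate_scans(cfg)
  q <- quantify_experiment(sim$ids, sim$scans, run_config(p = 0.97))
  missing <- sim$truth$accession[sim$truth$kind == "missing_heavy"]
  expect_true(all(is.infinite(q$ratio[q$accession %in% missing])))
  expect_true(all(is.finite(q$ratio[!q$accession %in% missing])))
  expect_equal(nrow(q), 8)  # every identification quantified, none discarded
})

test_that("ratios are invariant to global intensity scaling", {
  cfg <- sim_config(n_proteins = 2, peptides_per_protein = 2, ratios = 1.5,
                    p = 0.96, noise_cv = 0, rt_range = c(60, 150), seed = 17)
  sim <- simulate_scans(cfg)
  scaled <- structure(lapply(sim$scans, function(s) {
    s$peaks[, "intensity"] <- s$peaks[, "intensity"] * 37
    s
  }), class = "ms1_scans")
  q1 <- quantify_experiment(sim$ids, sim$scans, run_config(p = 0.96))
  q2 <- quantify_experiment(sim$ids, scaled, run_config(p = 0.96))
  expect_equal(q1$ratio, q2$ratio, tolerance = 1e-12)
})

test_that("swapping channel labels inverts the ratio", {
  cfg <- sim_config(n_proteins = 3, peptides_per_protein = 3, ratios = 3,
                    p = 0.97, noise_cv = 0, rt_range = c(60, 200), seed = 18)
  fwd <- simulate_scans(cfg)
  cfg_rev <- cfg; cfg_rev$ratios <- 1 / 3
  rev <- simulate_scans(cfg_rev)
  qf <- quantify_experiment(fwd$ids, fwd$scans, run_config(p = 0.97))
  qr <- quantify_experiment(rev$ids, rev$scans, run_config(p = 0.97))
  expect_equal(median(qf$ratio) * median(qr$ratio), 1, tolerance = 0.01)
})

test_that("co-eluting contamination lowers the affected channel's CS score", {
  cfg <- sim_config(n_proteins = 4, peptides_per_protein = 2, ratios = 1,
                    p = 0.95, n_interference = 4, interference_offset = 0,
                    interference_scale = 3, rt_range = c(60, 250), seed = 19)
  sim <- simulate_scans(cfg)
  q <- quantify_experiment(sim$ids, sim$scans, run_config(p = 0.95))
  key <- paste(q$sequence, q$charge)
  tkey <- paste(sim$truth$sequence, sim$truth$charge)
  hit <- sim$truth$interfered[match(key, tkey)]
  expect_true(all(q$cs_heavy[hit] < q$cs_light[hit]))
  expect_lt(max(q$cs_heavy[hit]), min(q$cs_heavy[!hit]))
})

test_that("duplicate identifications collapse to one quant anchored at the top score", {
  cfg <- sim_config(n_proteins = 2, peptides_per_protein = 2, ratios = 1,
                    p = 0.97, rt_range = c(60, 150), seed = 20)
  sim <- simulate_scans(cfg)
  dup <- sim$ids[1, ]
  dup$channel <- if (dup$channel == "light") "heavy" else "light"
  dup$score <- sim$ids$score[1] + 10
  dup$rt <- dup$rt + 1
  ids2 <- rbind(sim$ids, dup)
  q <- quantify_experiment(ids2, sim$scans, run_config(p = 0.97))
  expect_equal(nrow(q), nrow(sim$ids))
  i <- which(q$sequence == dup$sequence & q$charge == dup$charge)
  expect_equal(q$rt[i], dup$rt)  # higher-score record anchors the window
})
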