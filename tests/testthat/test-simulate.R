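# Simulator: determinism, ground-truth fidelity, and the cache/report and
# CLI wiring around it.

test_that("the seed fully determines simulator output", {
  cfg <- sim_config(n_proteins = 3, peptides_per_protein = 2,
                    rt_range = c(60, 120), seed = 77)
  a <- simulate_scans(cfg)
  b <- simulate_scans(cfg)
  expect_identical(a$ids, b$ids)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$scans, `[[`, "peaks"),
                   lapply(b$scans, `[[`, "peaks"))
  c2 <- simulate_scans(sim_config(n_proteins = 3, peptides_per_protein = 2,
                                  rt_range = c(60, 120), seed = 78))
  expect_false(identical(a$scans[[1]]$peaks, c2$scans[[1]]$peaks))
})

test_that("generated files round-trip and carry matching ground truth", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 2, peptides_per_protein = 2,
                    rt_range = c(60, 100), seed = 5)
  paths <- generate_experiment(cfg, dir)
  expect_true(all(file.exists(paths)))
  ids <- read_id_table(paths["ids"])
  truth <- read.delim(paths["truth"])
  expect_setequal(ids$sequence, truth$sequence)
  scans <- read_ms1(paths["mzml"])
  expect_gt(length(scans), 10)
})

test_that("simulated cluster peaks reproduce the theoretical envelope shape", {
  cfg <- sim_config(n_proteins = 2, peptides_per_protein = 1, ratios = 1,
                    p = 0.94, noise_cv = 0, rt_range = c(100, 140), seed = 6)
  sim <- simulate_scans(cfg)
  tr <- sim$truth[1, ]
  comp <- build_composition(peptide_ion(tr$sequence, "", tr$charge, "heavy"))
  env <- envelope(comp, 0.94)
  slice <- average_scans(sim$scans, tr$apex_rt)
  obs <- vapply(env$mz, function(mz) match_peak(slice, mz)$intensity,
                numeric(1))
  keep <- env$abundance > 1e-3
  expect_equal(obs[keep] / sum(obs[keep]),
               env$abundance[keep] / sum(env$abundance[keep]),
               tolerance = 1e-6)
})

test_that("noiseless 1:1 runs recover unit medians end to end", {
  cfg <- sim_config(n_proteins = 4, peptides_per_protein = 3, ratios = 1,
                    p = 0.97, noise_cv = 0, rt_range = c(60, 260), seed = 88)
  sim <- simulate_scans(cfg)
  q <- quantify_experiment(sim$ids, sim$scans, run_config(p = 0.97))
  p <- protein_stats(q)
  expect_equal(p$median, rep(1, 4), tolerance = 1e-3)
})

test_that("unlabeled (seed-storage) proteins appear light-only in the mix", {
  cfg <- sim_config(n_proteins = 3, peptides_per_protein = 2, ratios = 1,
                    p = 0.97, n_unlabeled = 1, rt_range = c(60, 200), seed = 9)
  sim <- simulate_scans(cfg)
  un <- sim$truth[sim$truth$kind == "unlabeled", ]
  expect_true(all(un$heavy_total == 0))
  q <- quantify_experiment(sim$ids, sim$scans, run_config(p = 0.97))
  expect_true(all(is.infinite(q$ratio[q$accession %in% un$accession])))
})

test_that("contradictory configurations are rejected", {
  expect_error(sim_config(ratios = Inf), "finite")
  expect_error(sim_config(ratios = -1), "positive")
  expect_error(sim_config(n_proteins = 2, n_missing_heavy = 2, n_unlabeled = 1),
               "more missing")
  expect_error(sim_config(p = 1.5), "\\(0, 1\\]")
})

test_that("cache round trip regenerates byte-identical reports without mzML", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 3, peptides_per_protein = 3,
                    ratios = c(0.5, 1, 2), p = 0.96, n_missing_heavy = 1,
                    rt_range = c(60, 200), seed = 10)
  paths <- generate_experiment(cfg, dir)
  scans <- read_ms1(paths["mzml"])
  ids <- read_id_table(paths["ids"])
  q <- quantify_experiment(ids, scans, run_config(p = 0.96))
  cache <- file.path(dir, "cache.json")
  write_cache(q, cache)
  # original reports straight from the in-memory quantification
  orig <- c(file.path(dir, "orig_peptides.tsv"),
            file.path(dir, "orig_proteins.tsv"))
  write_peptide_report(q, orig[1])
  write_protein_report(
    suppressWarnings(normalize_proteins(protein_stats(q))), orig[2])
  # remove the raw data entirely: regeneration must not need it
  file.remove(paths["mzml"])
  again <- suppressWarnings(
    regenerate_reports(cache, file.path(dir, "again")))
  expect_identical(readBin(orig[1], "raw", file.size(orig[1])),
                   readBin(again[1], "raw", file.size(again[1])))
  expect_identical(readBin(orig[2], "raw", file.size(orig[2])),
                   readBin(again[2], "raw", file.size(again[2])))
  # sentinels survive the JSON round trip
  q2 <- read_cache(cache)
  expect_identical(is.infinite(q2$ratio), is.infinite(q$ratio))
  expect_error(read_cache(file.path(dir, "truth.tsv")))
})

test_that("cache schema version mismatches are explicit", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(schema_version = "other-9", quants = list()),
                       bad, auto_unbox = TRUE)
  expect_error(read_cache(bad), "schema version mismatch")
})
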