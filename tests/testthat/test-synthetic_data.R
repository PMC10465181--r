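test_that("generators are pure functions of (config, seed)", {
  cfg <- tiny_config(42)
  t1 <- gen_truth(cfg)
  t2 <- gen_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(gen_od_curves(cfg, t1), gen_od_curves(cfg, t2))
  expect_identical(gen_gdgt_peaks(cfg, t1), gen_gdgt_peaks(cfg, t1))
  expect_identical(gen_counts(cfg, t1), gen_counts(cfg, t1))
  expect_identical(gen_protein_quants(cfg, t1), gen_protein_quants(cfg, t1))
  # different seeds give different data
  expect_false(identical(gen_counts(tiny_config(43), gen_truth(tiny_config(43))),
                         gen_counts(cfg, t1)))
})

test_that("config validation rejects non-positive and out-of-range values", {
  expect_error(generator_config(n_genes = 0), "n_genes")
  expect_error(generator_config(frac_de = 1.2), "frac_de")
  expect_error(generator_config(dirichlet_concentration = 0), "dirichlet")
  expect_error(generator_config(od_noise_sd = -1), "SDs")
  expect_error(generator_config(protein_shift_size = 0.5), "at least 1")
})

test_that("truth manifest round-trips through JSON", {
  cfg <- tiny_config(5)
  truth <- gen_truth(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  for (tab in c("growth", "lipids", "genes", "proteins")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(truth[[tab]]),
                 tolerance = 1e-12)
  }
  expect_equal(back$seed, truth$seed)
})

test_that("true lipid compositions sit on the simplex at the target ring index", {
  truth <- gen_truth(tiny_config(1))
  f <- as.matrix(truth$lipids[, paste0("GDGT-", 0:8)])
  expect_equal(rowSums(f), rep(1, 6), tolerance = 1e-9)
  ri <- as.numeric(f %*% (0:8))
  expect_equal(ri, truth$lipids$ri, tolerance = 1e-9)
  expect_equal(sort(unique(truth$lipids$ri)),
               sort(c(3.65, 3.93, 1.59, 2.08, 2.83, 3.67)))
  # rings 7 and 8 carry (essentially) no mass
  expect_true(all(f[, "GDGT-7"] < 0.01))
  expect_true(all(f[, "GDGT-8"] == 0))
})

test_that("noiseless OD curves follow the logistic closed form", {
  cfg <- tiny_config(3, od_noise_sd = 0, od_horizon = 400, od_interval = 4)
  truth <- gen_truth(cfg)
  od <- gen_od_curves(cfg, truth)
  first <- od[od$time == 0, ]
  expect_equal(first$od, rep(0.02, nrow(first)), tolerance = 1e-12)
  # long-time asymptote reaches the per-condition carrying capacity
  meta <- dplyr::inner_join(od[od$time == max(od$time), ],
                            design_samples(), by = "sample_id")
  meta <- dplyr::inner_join(meta, truth$growth, by = "condition")
  expect_equal(meta$od, meta$K, tolerance = 1e-6)
  # early local slope of ln(OD) approximates mu (finite differences)
  one <- od[od$sample_id == "optimal_ES_r1" & od$time <= 12, ]
  slope <- diff(log(one$od)) / diff(one$time)
  mu <- truth$growth$mu[truth$growth$condition == "optimal"]
  expect_equal(mean(slope), mu, tolerance = 0.05)
})

test_that("Dirichlet compositions normalize and collapse to truth at high concentration", {
  cfg <- tiny_config(9)
  truth <- gen_truth(cfg)
  peaks <- gen_gdgt_peaks(cfg, truth)
  merged <- merge_isomers(peaks)
  comp <- relative_abundance(merged)
  expect_equal(rowSums(as.matrix(comp[, paste0("f_", 0:8)])), rep(1, 18),
               tolerance = 1e-9)

  # isomer split conserves per-sample total area exactly
  tot_before <- rowSums(as.matrix(peaks[, setdiff(names(peaks), "sample_id")]))
  tot_after <- rowSums(as.matrix(merged[, setdiff(names(merged), "sample_id")]))
  expect_equal(tot_before, tot_after, tolerance = 1e-9)

  # degenerate limit: enormous concentration pins samples to the truth
  cfg_hi <- tiny_config(9, dirichlet_concentration = 1e9)
  comp_hi <- relative_abundance(merge_isomers(gen_gdgt_peaks(cfg_hi, truth)))
  dat <- dplyr::inner_join(comp_hi, design_samples(), by = "sample_id") |>
    dplyr::inner_join(truth$lipids, by = c("condition", "phase"))
  for (n in 0:8) {
    expect_equal(dat[[paste0("f_", n)]], dat[[paste0("GDGT-", n)]],
                 tolerance = 1e-3)
  }
})

test_that("mean simulated ring index matches the configured target", {
  # Monte-Carlo check on the optimal/mid-log cell: >= 1000 Dirichlet draws
  cfg <- generator_config(n_genes = 2, n_proteins = 2, seed = 21)
  truth <- gen_truth(cfg)
  f_true <- as.numeric(
    truth$lipids[truth$lipids$condition == "optimal" &
                   truth$lipids$phase == "mid_log", paste0("GDGT-", 0:8)]
  )
  ris <- withr::with_seed(99, vapply(seq_len(1000), function(i) {
    g <- stats::rgamma(9, shape = cfg$dirichlet_concentration * f_true)
    sum((0:8) * g / sum(g))
  }, numeric(1)))
  expect_equal(mean(ris), 3.65, tolerance = 0.05)
})

test_that("count generator honors truth effects and the stress sign convention", {
  cfg0 <- tiny_config(7, frac_de = 0)
  truth0 <- gen_truth(cfg0)
  lfc_cols <- design_contrasts()$contrast
  expect_true(all(as.matrix(truth0$genes[, lfc_cols]) == 0))

  # negative true log2FC means increased expression under stress
  cfg <- tiny_config(8, dispersion = 0, lib_size_jitter = 0)
  truth <- gen_truth(cfg)
  truth$genes$base_mean <- rep(10000, nrow(truth$genes))
  truth$genes$acid_vs_optimal_ML <- 0
  truth$genes$acid_vs_optimal_ML[1] <- -2
  counts <- gen_counts(cfg, truth)
  mat <- as.matrix(counts[, -1])
  acid_ml <- design_samples()$sample_id[design_samples()$condition == "acid" &
                                          design_samples()$phase == "mid_log"]
  opt_ml <- design_samples()$sample_id[design_samples()$condition == "optimal" &
                                         design_samples()$phase == "mid_log"]
  ratio <- mean(mat[1, acid_ml]) / mean(mat[1, opt_ml])
  expect_equal(log2(ratio), 2, tolerance = 0.1)
  expect_true(all(mat >= 0))
})

test_that("protein quantification collapses to truth when all noise is off", {
  cfg <- tiny_config(4, spectral_sd = 0, between_sd = 0,
                     frac_protein_shift = 0.2)
  truth <- gen_truth(cfg)
  quants <- gen_protein_quants(cfg, truth)
  expect_true(all(quants$within_se == 0))
  cells <- paste(design_samples()$condition, design_samples()$phase, sep = ".")
  idx_s <- match(quants$sample_id, design_samples()$sample_id)
  idx_p <- match(quants$protein_id, truth$proteins$protein_id)
  expected <- as.matrix(
    truth$proteins[, setdiff(names(truth$proteins), c("protein_id", "shifted"))]
  )[cbind(idx_p, match(cells[idx_s], colnames(truth$proteins)[-(1:2)]))]
  expect_equal(quants$log2_ratio, expected, tolerance = 1e-12)
  expect_true(all(quants$n_spectra >= 1))
})

test_that("simulate_all writes a complete, reloadable input set", {
  out <- withr::local_tempdir()
  cfg <- tiny_config(6)
  simulate_all(cfg, out)
  for (f in c("design.tsv", "od_series.tsv", "gdgt_peaks.tsv", "counts.tsv",
              "protein_quants.tsv", "truth.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  expect_equal(nrow(read_table(file.path(out, "design.tsv"), "design")), 18)
  expect_equal(read_truth(file.path(out, "truth.json"))$seed, 6L)
})
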