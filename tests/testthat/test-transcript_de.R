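qc_design <- function() {
  tibble::tibble(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3)),
    condition = rep(c("optimal", "acid"), each = 3),
    phase = "mid_log",
    replicate = rep(1:3, 2)
  )
}

test_that("replicate QC applies the pass / retain / exclude rule", {
  withr::with_seed(5, {
    base_a <- rpois(200, 100)
    base_b <- rpois(200, 400)
    jitter <- function(v, sd) pmax(0, round(v + rnorm(length(v), 0, sd)))
    counts <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:200),
      a1 = jitter(base_a, 1), a2 = jitter(base_a, 1),
      a3 = jitter(base_a, 25),               # noisy replicate, still in-group
      b1 = jitter(base_b, 2), b2 = jitter(base_b, 2), b3 = jitter(base_b, 2)
    )
  })
  qc <- replicate_qc(counts, qc_design())
  expect_true(all(qc$status[qc$sample_id %in% c("a1", "a2", "b1", "b2", "b3")] ==
                    "pass"))
  a3 <- qc[qc$sample_id == "a3", ]
  expect_lte(a3$r_in, 0.9)
  expect_lte(a3$r_out, a3$r_in + 0.05)
  expect_equal(a3$status, "retained_with_warning")
})

test_that("a library correlating better outside its group is excluded", {
  withr::with_seed(6, {
    base_a <- rpois(200, 100)
    base_b <- rpois(200, 400)
    jitter <- function(v, sd) pmax(0, round(v + rnorm(length(v), 0, sd)))
    counts <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:200),
      a1 = jitter(base_a, 3), a2 = jitter(base_a, 3),
      a3 = jitter(base_b, 3),                # looks like the other group
      b1 = jitter(base_b, 5), b2 = jitter(base_b, 5), b3 = jitter(base_b, 5)
    )
  })
  qc <- replicate_qc(counts, qc_design())
  expect_equal(qc$status[qc$sample_id == "a3"], "excluded")
})

test_that("identical libraries pass QC with r_in = 1 and constants error", {
  v <- withr::with_seed(8, rpois(100, 50))
  counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                           a1 = v, a2 = v, a3 = v, b1 = v + 1L, b2 = v + 2L,
                           b3 = v + 3L)
  qc <- replicate_qc(counts, qc_design())
  expect_equal(qc$r_in[qc$sample_id %in% c("a1", "a2", "a3")], rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(qc$status == "pass"))

  counts$a2 <- 7L
  expect_error(replicate_qc(counts, qc_design()), "a2")
})

test_that("log2-CPM normalization matches direct arithmetic", {
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"),
    lib1 = c(1000L, 999000L),  # total exactly 1e6
    lib2 = c(0L, 100L)
  )
  norm <- normalize_counts(counts)
  expect_equal(norm["g1", "lib1"], log2(1000.5), tolerance = 1e-12)
  expect_equal(norm["g1", "lib2"], log2(0.5), tolerance = 1e-12)
  # doubling all counts leaves CPM unchanged (up to the pseudocount)
  doubled <- counts
  doubled[, -1] <- doubled[, -1] * 2L
  expect_equal(normalize_counts(doubled), norm, tolerance = 1e-12)

  zero <- tibble::tibble(gene_id = "g1", lib1 = 0L)
  expect_error(normalize_counts(zero), "zero-total")
})

test_that("the stand-in DE test recovers planted effects with the stated sign", {
  cfg <- tiny_config(12, dispersion = 0, lib_size_jitter = 0, n_genes = 200)
  truth <- gen_truth(cfg)
  truth$genes$base_mean <- rep(5000, nrow(truth$genes))
  for (ctr in design_contrasts()$contrast) truth$genes[[ctr]] <- 0
  truth$genes$acid_vs_optimal_ML[1] <- -2   # up in stress
  truth$genes$acid_vs_optimal_ML[2] <- 1.5  # down in stress
  counts <- gen_counts(cfg, truth)
  ctr <- design_contrasts()[design_contrasts()$contrast == "acid_vs_optimal_ML", ]
  de <- de_test_standin(counts, ctr)
  expect_equal(de$log2FC[1], -2, tolerance = 0.15)
  expect_equal(de$log2FC[2], 1.5, tolerance = 0.15)
  expect_lt(de$padj[1], 0.05)

  # filtered low-count genes never become DEGs
  low_counts <- counts
  low_counts[3, -1] <- as.list(rep(1L, 18))
  de_low <- de_test_standin(low_counts, ctr)
  expect_true(is.na(de_low$padj[3]))
  expect_false("gene_0003" %in% call_degs(de_low)$gene_id)
})

test_that("identical groups give zero fold change and p = 1", {
  samples <- design_samples()
  ml <- samples$sample_id[samples$phase == "mid_log"]
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:10))
  for (s in samples$sample_id) counts[[s]] <- rep(100L, 10)
  ctr <- design_contrasts()[1, ]
  de <- de_test_standin(counts, ctr)
  expect_true(all(de$log2FC == 0))
  expect_true(all(de$pvalue == 1))
})

test_that("estimated log2FC flips sign exactly under group swap", {
  cfg <- tiny_config(13, n_genes = 100)
  counts <- gen_counts(cfg, gen_truth(cfg))
  ctr <- design_contrasts()[2, ]
  de <- de_test_standin(counts, ctr)
  swapped <- ctr
  swapped$stress <- ctr$baseline
  swapped$baseline <- ctr$stress
  de_sw <- de_test_standin(counts, swapped)
  expect_equal(de_sw$log2FC, -de$log2FC, tolerance = 1e-12)
})

test_that("DEG calls respect both thresholds and the sign convention", {
  de <- tibble::tibble(
    gene_id = c("grsB_like", "down1", "edge", "filtered", "weak"),
    contrast = "acid_vs_optimal_ML",
    log2FC = c(-2.1, 2.5, -0.9, -3, -1.5),
    pvalue = c(1e-5, 1e-4, 1e-10, NA, 0.2),
    padj = c(1e-4, 1e-3, 1e-9, NA, 0.4)
  )
  calls <- call_degs(de)
  expect_equal(calls$direction[calls$gene_id == "grsB_like"], "up_in_stress")
  expect_equal(calls$direction[calls$gene_id == "down1"], "down_in_stress")
  expect_false("edge" %in% calls$gene_id)      # |log2FC| < 1
  expect_false("filtered" %in% calls$gene_id)  # NA padj
  expect_false("weak" %in% calls$gene_id)      # padj too high
})

test_that("the Venn partition enumerates unique and common responses", {
  mk <- function(genes, dirs, contrast) {
    tibble::tibble(gene_id = genes, contrast = contrast, direction = dirs)
  }
  acid <- mk(c("g1", "g2"), c("up_in_stress", "down_in_stress"),
             "acid_vs_optimal_ML")
  cold <- mk(c("g1", "g3"), c("up_in_stress", "up_in_stress"),
             "cold_vs_optimal_ML")
  v <- venn_partition(acid, cold, "mid_log")
  up <- v[v$direction == "up_in_stress", ]
  down <- v[v$direction == "down_in_stress", ]
  expect_equal(up$n_common, 1)
  expect_equal(up$n_unique_cold, 1)
  expect_equal(down$n_unique_acid, 1)
  expect_equal(down$n_common, 0)
  tot <- v[v$direction == "total", ]
  expect_equal(tot$n_total_acid, 2)
  expect_equal(tot$n_total_cold, 2)

  # disjoint and identical sets
  expect_equal(venn_partition(acid, mk("g9", "up_in_stress", "cold_vs_optimal_ML"),
                              "mid_log")$n_common, c(0, 0, 0))
  same_cold <- mk(c("g1", "g2"), c("up_in_stress", "down_in_stress"),
                  "cold_vs_optimal_ML")
  vi <- venn_partition(acid, same_cold, "mid_log")
  expect_equal(vi$n_common[vi$direction == "total"], 2)
  expect_equal(sum(vi$n_unique_acid), 0)

  # phase mismatch is an error
  expect_error(venn_partition(acid, cold, "early_stationary"), "phase")
})
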