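# Transcript sign convention used throughout this module: log2FC is
# mean(optimal) - mean(stress) on the log2 scale, so NEGATIVE log2FC means
# increased expression under stress. This is inverted relative to common
# DE-tool defaults; the protein module uses the opposite (positive =
# increased under stress), and the concordance step reconciles the two.

counts_matrix <- function(counts) {
  mat <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop("negative entries in count matrix", call. = FALSE)
  mat
}

#' Replicate-correlation quality control
#'
#' Pearson correlation between libraries on raw counts. For every library,
#' `r_in` is its highest correlation with another member of its replicate
#' group (same condition and phase) and `r_out` its highest correlation
#' with any library outside the group. A library passes when `r_in > 0.9`;
#' otherwise it is retained with a warning unless some outside library
#' correlates better by more than 0.05 (`r_out > r_in + 0.05`), in which
#' case it is excluded.
#'
#' @param counts A counts tibble (`gene_id` plus one column per library).
#' @param design The sample design.
#' @param r_min Within-group pass threshold (default 0.9).
#' @param margin Exclusion margin on `r_out` (default 0.05).
#' @return A tibble `sample_id`, `r_in`, `r_out`, `status`.
#' @export
replicate_qc <- function(counts, design = design_samples(),
                         r_min = 0.9, margin = 0.05) {
  mat <- counts_matrix(counts)
  libs <- colnames(mat)
  const <- apply(mat, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("constant library (undefined correlation): ",
         paste(libs[const], collapse = ", "), call. = FALSE)
  }
  meta <- design[match(libs, design$sample_id), ]
  if (anyNA(meta$condition)) stop("library missing from design", call. = FALSE)
  group <- paste(meta$condition, meta$phase)
  n_in_group <- table(group)
  if (any(n_in_group < 2)) stop("need >= 2 libraries per replicate group", call. = FALSE)
  cm <- stats::cor(mat)
  purrr::map_dfr(seq_along(libs), function(i) {
    grp <- group == group[i]
    in_mask <- grp
    in_mask[i] <- FALSE
    out_mask <- !grp
    r_in <- max(cm[i, in_mask])
    r_out <- if (any(out_mask)) max(cm[i, out_mask]) else NA_real_
    status <- if (r_in > r_min) {
      "pass"
    } else if (!is.na(r_out) && r_out > r_in + margin) {
      "excluded"
    } else {
      "retained_with_warning"
    }
    tibble::tibble(sample_id = libs[i], r_in = r_in, r_out = r_out,
                   status = status)
  })
}

#' Log2 counts-per-million normalization
#'
#' Scales every library to one million, then takes `log2(cpm + 0.5)`.
#'
#' @param counts A counts tibble.
#' @return A numeric matrix (genes x libraries) of log2 CPM values.
#' @export
normalize_counts <- function(counts) {
  mat <- counts_matrix(counts)
  totals <- colSums(mat)
  if (any(totals == 0)) {
    stop("zero-total library: ",
         paste(colnames(mat)[totals == 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(mat, 2, totals / 1e6, `/`) + 0.5)
}

row_var <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Stand-in differential expression test
#'
#' A deliberately simple per-gene Welch t-test on log2 CPM values for one
#' stress-versus-optimal contrast, provided so that synthetic data can flow
#' through the downstream DEG accounting end to end. It is NOT a
#' replacement for a dedicated count-based DE tool on real data; externally
#' produced result tables can be supplied to [call_degs()] instead.
#'
#' Genes whose mean raw count across the contrast's libraries falls below
#' `count_floor` are reported with `pvalue = padj = NA` and can never
#' become DEGs (the analogue of independent filtering). log2FC is
#' `mean(optimal) - mean(stress)` (negative = up in stress); p-values are
#' Benjamini-Hochberg adjusted within the contrast.
#'
#' @param counts A counts tibble.
#' @param contrast One row of [design_contrasts()] (or a matching list with
#'   `stress`, `phase`, `baseline`, `contrast`).
#' @param design The sample design.
#' @param count_floor Mean-raw-count filter threshold.
#' @return A tibble `gene_id`, `contrast`, `log2FC`, `pvalue`, `padj`.
#' @export
de_test_standin <- function(counts, contrast, design = design_samples(),
                            count_floor = 5) {
  raw <- counts_matrix(counts)
  norm <- normalize_counts(counts)
  stress_ids <- design$sample_id[design$condition == contrast$stress &
                                   design$phase == contrast$phase]
  base_ids <- design$sample_id[design$condition == contrast$baseline &
                                 design$phase == contrast$phase]
  stress_ids <- intersect(stress_ids, colnames(norm))
  base_ids <- intersect(base_ids, colnames(norm))
  if (length(stress_ids) < 2 || length(base_ids) < 2) {
    stop("need >= 2 replicates on each side of the contrast", call. = FALSE)
  }
  s <- norm[, stress_ids, drop = FALSE]
  b <- norm[, base_ids, drop = FALSE]
  ns <- ncol(s); nb <- ncol(b)
  ms <- rowMeans(s); mb <- rowMeans(b)
  vs <- row_var(s); vb <- row_var(b)
  lfc <- mb - ms
  denom2 <- vs / ns + vb / nb
  tstat <- ifelse(denom2 > 0, lfc / sqrt(denom2), 0)
  df <- ifelse(denom2 > 0,
               denom2^2 / ((vs / ns)^2 / (ns - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(denom2 > 0,
              2 * stats::pt(-abs(tstat), df),
              ifelse(abs(lfc) < 1e-12, 1, 0))
  low <- rowMeans(raw[, c(stress_ids, base_ids), drop = FALSE]) < count_floor
  p[low] <- NA_real_
  tibble::tibble(
    gene_id = rownames(norm),
    contrast = contrast$contrast,
    log2FC = unname(lfc),
    pvalue = unname(p),
    padj = bh_adjust(unname(p))
  )
}

#' Call differentially expressed genes
#'
#' A gene is a DEG for a contrast when `|log2FC| >= lfc_min` (default 1,
#' i.e. at least twofold) and `padj < padj_max` (default 0.05). Direction
#' follows the transcript sign convention: `log2FC <= -lfc_min` is
#' `up_in_stress`, `log2FC >= lfc_min` is `down_in_stress`. Rows with `NA`
#' adjusted p-values are never called.
#'
#' @param de A DE result tibble (`gene_id`, `contrast`, `log2FC`, `padj`).
#' @param lfc_min,padj_max Call thresholds.
#' @return A tibble `gene_id`, `contrast`, `direction`.
#' @export
call_degs <- function(de, lfc_min = 1, padj_max = 0.05) {
  de |>
    dplyr::filter(!is.na(.data$padj),
                  .data$padj < padj_max,
                  abs(.data$log2FC) >= lfc_min) |>
    dplyr::mutate(direction = ifelse(.data$log2FC <= 0,
                                     "up_in_stress", "down_in_stress")) |>
    dplyr::select("gene_id", "contrast", "direction")
}

#' Cross-stress Venn partition of DEG responses
#'
#' A DEG response is the pair (gene, direction of change). For one phase,
#' responses are split into those unique to acid stress, unique to cold
#' stress, and common to both, per direction and in total. The partition
#' conserves totals by construction: unique + common equals each stress's
#' directional DEG count, and this is asserted on every call.
#'
#' @param degs_acid,degs_cold DEG call tibbles for the acid and cold
#'   contrasts of one phase.
#' @param phase The phase both inputs must belong to.
#' @param design_ctr The contrast table (used to check phases).
#' @return A tibble with rows per direction plus a `total` row: `phase`,
#'   `direction`, `n_unique_acid`, `n_unique_cold`, `n_common`,
#'   `n_total_acid`, `n_total_cold`.
#' @export
venn_partition <- function(degs_acid, degs_cold, phase,
                           design_ctr = design_contrasts()) {
  check_phase <- function(degs, stress) {
    if (nrow(degs) == 0) return(invisible())
    ph <- design_ctr$phase[match(unique(degs$contrast), design_ctr$contrast)]
    if (any(is.na(ph)) || any(ph != phase)) {
      stop("DEG calls for ", stress, " do not all belong to phase '", phase,
           "'", call. = FALSE)
    }
  }
  check_phase(degs_acid, "acid")
  check_phase(degs_cold, "cold")
  key <- function(d) paste(d$gene_id, d$direction)
  rows <- purrr::map_dfr(c("up_in_stress", "down_in_stress"), function(dir) {
    a <- key(degs_acid[degs_acid$direction == dir, ])
    c_ <- key(degs_cold[degs_cold$direction == dir, ])
    tibble::tibble(
      phase = phase, direction = dir,
      n_unique_acid = length(setdiff(a, c_)),
      n_unique_cold = length(setdiff(c_, a)),
      n_common = length(intersect(a, c_)),
      n_total_acid = length(a),
      n_total_cold = length(c_)
    )
  })
  total <- rows |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("n_"), sum)) |>
    dplyr::mutate(phase = phase, direction = "total", .before = 1)
  out <- dplyr::bind_rows(rows, total)
  stopifnot(
    out$n_unique_acid + out$n_common == out$n_total_acid,
    out$n_unique_cold + out$n_common == out$n_total_cold
  )
  out
}
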