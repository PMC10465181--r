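# Differential protein abundance via a layered-uncertainty Z statistic.
#
# Per protein and condition (at one phase), the total uncertainty u combines
# the SD of the protein's mean log2 abundance across biological replicates
# with the average within-replicate spectral SE, in quadrature by default:
#   u = sqrt(sd_between^2 + se_within_avg^2).
# The test statistic for a stress-versus-optimal contrast is
#   Z = (m_stress - m_optimal) / (u_stress + u_optimal),
# with a PLAIN SUM in the denominator. Because u carries the full
# between-replicate SD (not the SE of the mean) and the two u's add
# linearly, the procedure is deliberately conservative. Z is referred to a
# standard normal; p-values are Benjamini-Hochberg adjusted and calls
# additionally require at least a twofold change (|log2FC| >= 1).
#
# Protein sign convention: log2FC = m_stress - m_optimal, POSITIVE =
# increased abundance under stress (opposite to the transcript convention).

#' Per-condition protein summary with layered uncertainty
#'
#' For every protein quantified in the given condition and phase:
#' `m` = mean of the per-replicate log2 ratios, `sd_between` = their sample
#' SD, `se_within_avg` = mean of the reported within-replicate spectral
#' SEs, and the total uncertainty `u`, combining the two layers in
#' quadrature (`sqrt(sd_between^2 + se_within_avg^2)`) or additively.
#' Proteins seen in fewer than two replicates get `u = NA` and are excluded
#' from testing downstream.
#'
#' @param quants A protein quantification tibble (`protein_id`, `sample_id`,
#'   `log2_ratio`, `within_se`, `n_spectra`).
#' @param condition,phase The group to summarize.
#' @param design The sample design.
#' @param combine `"quadrature"` (default) or `"additive"`.
#' @return A tibble `protein_id`, `condition`, `phase`, `m`, `sd_between`,
#'   `se_within_avg`, `u`, `n_reps`.
#' @export
condition_summary <- function(quants, condition, phase,
                              design = design_samples(),
                              combine = c("quadrature", "additive")) {
  combine <- match.arg(combine)
  if (any(quants$within_se < 0, na.rm = TRUE)) {
    stop("within_se must be >= 0", call. = FALSE)
  }
  ids <- design$sample_id[design$condition == condition & design$phase == phase]
  dat <- quants[quants$sample_id %in% ids, ]
  if (anyDuplicated(dat[, c("protein_id", "sample_id")])) {
    stop("duplicate protein x sample rows", call. = FALSE)
  }
  cond <- condition
  ph <- phase
  dat |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      m = mean(.data$log2_ratio),
      sd_between = if (dplyr::n() >= 2) stats::sd(.data$log2_ratio) else NA_real_,
      se_within_avg = mean(.data$within_se),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      condition = cond, phase = ph,
      u = dplyr::case_when(
        n_reps < 2 ~ NA_real_,
        combine == "quadrature" ~ sqrt(sd_between^2 + se_within_avg^2),
        TRUE ~ sd_between + se_within_avg
      )
    ) |>
    dplyr::select("protein_id", "condition", "phase", "m", "sd_between",
                  "se_within_avg", "u", "n_reps")
}

#' Z-score for a protein abundance difference
#'
#' `Z = (m_stress - m_optimal) / (u_stress + u_optimal)`. A zero
#' denominator with zero numerator yields `Z = 0` (with a warning); a zero
#' denominator with nonzero numerator yields a signed infinity, mapped to
#' p = 0 downstream.
#'
#' @param m_stress,m_optimal Mean log2 abundances in the two conditions.
#' @param u_stress,u_optimal Total uncertainties in the two conditions.
#' @return Numeric Z (vectorized).
#' @export
z_score <- function(m_stress, m_optimal, u_stress, u_optimal) {
  num <- m_stress - m_optimal
  den <- u_stress + u_optimal
  zero_den <- !is.na(den) & den == 0
  if (any(zero_den & !is.na(num) & num == 0)) {
    warning("zero uncertainty with zero difference: Z set to 0")
  }
  ifelse(zero_den,
         ifelse(num == 0, 0, sign(num) * Inf),
         num / den)
}

#' Two-sided normal p-value from a Z-score
#'
#' `p = 2 * (1 - Phi(|Z|))`; a one-sided value is available via
#' `alternative`.
#'
#' @param z Numeric Z-scores.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-values in \[0, 1\] (infinite Z maps to 0).
#' @export
p_from_z <- function(z, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1 and mapped back to
#' input order. `NA` entries are ignored for `m` and returned as `NA`.
#'
#' @param p Numeric p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok[o]] <- adj
  out
}

#' Flag significant protein abundance changes
#'
#' Significant iff `padj < padj_max` (default 0.1) AND
#' `|log2FC| >= lfc_min` (default 1, at least twofold).
#'
#' @param results A tibble with `log2FC` and `padj` columns.
#' @param padj_max,lfc_min Thresholds.
#' @return The tibble with a logical `significant` column added.
#' @export
classify_significant <- function(results, padj_max = 0.1, lfc_min = 1) {
  dplyr::mutate(
    results,
    significant = !is.na(.data$padj) & .data$padj < padj_max &
      abs(.data$log2FC) >= lfc_min
  )
}

#' Proteome coverage
#'
#' Share of the predicted proteome detected by the proteomic workflow.
#'
#' @param n_detected Number of distinct proteins detected.
#' @param n_predicted Number of proteins predicted in the genome.
#' @return A list with `percent` (raw) and `label` (rounded, e.g. "42%").
#' @export
#' @examples
#' proteome_coverage(1107, 2644)$label  # "42%"
proteome_coverage <- function(n_detected, n_predicted) {
  if (n_predicted <= 0 || n_detected < 0 || n_detected > n_predicted) {
    stop("need 0 <= n_detected <= n_predicted and n_predicted > 0",
         call. = FALSE)
  }
  pct <- 100 * n_detected / n_predicted
  list(percent = pct, label = paste0(round(pct), "%"))
}

#' Differential protein abundance across all contrasts
#'
#' Summarizes every protein per condition, computes the Z statistic per
#' stress-versus-optimal contrast, converts to normal p-values, adjusts
#' within each contrast (Benjamini-Hochberg), and flags calls at
#' `padj < padj_max` with `|log2FC| >= lfc_min`. Proteins not quantified in
#' at least two replicates of both conditions are carried through with NA
#' statistics, never dropped.
#'
#' @param quants A protein quantification tibble.
#' @param design The sample design.
#' @param contrasts Contrast table, as from [design_contrasts()].
#' @param padj_max,lfc_min Significance thresholds.
#' @param combine Uncertainty combination; see [condition_summary()].
#' @param alternative p-value sidedness; see [p_from_z()].
#' @return A tibble `protein_id`, `contrast`, `log2FC`, `Z`, `pvalue`,
#'   `padj`, `significant`.
#' @export
diff_protein_abundance <- function(quants, design = design_samples(),
                                   contrasts = design_contrasts(),
                                   padj_max = 0.1, lfc_min = 1,
                                   combine = "quadrature",
                                   alternative = "two.sided") {
  purrr::map_dfr(seq_len(nrow(contrasts)), function(k) {
    ph <- contrasts$phase[k]
    s_stress <- condition_summary(quants, contrasts$stress[k], ph,
                                  design = design, combine = combine)
    s_opt <- condition_summary(quants, contrasts$baseline[k], ph,
                               design = design, combine = combine)
    merged <- dplyr::full_join(
      s_stress, s_opt, by = "protein_id", suffix = c("_s", "_o")
    )
    z <- suppressWarnings(
      z_score(merged$m_s, merged$m_o, merged$u_s, merged$u_o)
    )
    res <- tibble::tibble(
      protein_id = merged$protein_id,
      contrast = contrasts$contrast[k],
      log2FC = merged$m_s - merged$m_o,
      Z = z,
      pvalue = ifelse(is.na(z), NA_real_, p_from_z(z, alternative = alternative))
    )
    res$padj <- bh_adjust(res$pvalue)
    classify_significant(res, padj_max = padj_max, lfc_min = lfc_min) |>
      dplyr::arrange(.data$protein_id)
  })
}
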