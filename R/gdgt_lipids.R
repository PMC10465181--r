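# GDGT nomenclature: columns "GDGT-0" .. "GDGT-8" hold peak areas for core
# tetraethers with 0..8 cyclopentane rings; "GDGT-np" is the late-eluting
# chromatographic isomer of GDGT-n (the prime in GDGT-n' written TSV-safe).

isomer_pattern <- "^GDGT-([0-8])p$"

#' Merge late-eluting isomer peaks into their major components
#'
#' Isomer columns (`GDGT-3p`, `GDGT-4p`, `GDGT-5p`, ...) are added to the
#' corresponding major ring column and dropped, conserving total area
#' exactly. Compositions and ring indices are always computed after this
#' merge.
#'
#' @param peaks A GDGT peak-area tibble with a `sample_id` column.
#' @return The tibble with isomer mass folded into the major columns.
#' @export
merge_isomers <- function(peaks) {
  iso_cols <- grep(isomer_pattern, names(peaks), value = TRUE)
  for (iso in iso_cols) {
    major <- sub("p$", "", iso)
    if (!major %in% names(peaks)) {
      stop("isomer column '", iso, "' has no major counterpart '", major, "'",
           call. = FALSE)
    }
    peaks[[major]] <- peaks[[major]] + peaks[[iso]]
  }
  peaks[, setdiff(names(peaks), iso_cols)]
}

#' Relative GDGT abundances
#'
#' Normalizes peak areas per sample to fractional abundances on the
#' simplex. Isomers must already be merged ([merge_isomers()]).
#'
#' @param peaks A merged GDGT peak-area tibble.
#' @return A tibble `sample_id`, `f_0` .. `f_8` with rows summing to 1.
#' @export
relative_abundance <- function(peaks) {
  if (any(grepl(isomer_pattern, names(peaks)))) {
    stop("isomer columns present; call merge_isomers() first", call. = FALSE)
  }
  cols <- intersect(gdgt_cols(), names(peaks))
  if (length(cols) == 0) stop("no GDGT columns found", call. = FALSE)
  areas <- as.matrix(peaks[, cols])
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak areas", call. = FALSE)
  totals <- rowSums(areas)
  if (any(totals <= 0)) {
    bad <- peaks$sample_id[which(totals <= 0)[1]]
    stop("sample '", bad, "' has zero total GDGT area", call. = FALSE)
  }
  frac <- matrix(0, nrow = nrow(areas), ncol = 9,
                 dimnames = list(NULL, paste0("f_", 0:8)))
  ring_of <- as.integer(sub("GDGT-", "", cols))
  frac[, paste0("f_", ring_of)] <- areas / totals
  dplyr::bind_cols(tibble::tibble(sample_id = peaks$sample_id),
                   tibble::as_tibble(frac))
}

#' Ring index of GDGT compositions
#'
#' The abundance-weighted mean number of cyclopentane rings:
#' `RI = sum(n * f_n, n = 1..8) / sum(f_n, n = 0..8)`, which reduces to
#' `sum(n * f_n)` for a normalized composition. RI is 0 when all mass sits
#' in GDGT-0 and at most 8.
#'
#' @param comp A composition tibble (`sample_id`, `f_0` .. `f_8`), as from
#'   [relative_abundance()].
#' @return A tibble `sample_id`, `ri`.
#' @export
#' @examples
#' comp <- tibble::tibble(sample_id = "s", f_0 = 0.5, f_1 = 0, f_2 = 0.5,
#'   f_3 = 0, f_4 = 0, f_5 = 0, f_6 = 0, f_7 = 0, f_8 = 0)
#' ring_index(comp)$ri  # 1
ring_index <- function(comp) {
  cols <- paste0("f_", 0:8)
  missing <- setdiff(cols, names(comp))
  if (length(missing) > 0) {
    stop("composition is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- as.matrix(comp[, cols])
  if (any(f < 0)) stop("negative abundances in composition", call. = FALSE)
  totals <- rowSums(f)
  if (any(totals <= 0)) stop("all-zero composition row", call. = FALSE)
  ri <- as.numeric(f %*% (0:8)) / totals
  tibble::tibble(sample_id = comp$sample_id, ri = ri)
}

#' Mean ring index per condition and phase
#'
#' @param ri A tibble `sample_id`, `ri` as from [ring_index()].
#' @param design The sample design.
#' @return A tibble `condition`, `phase`, `ri_mean`, `ri_se` (sd/sqrt(n)),
#'   `n`.
#' @export
summarize_condition <- function(ri, design = design_samples()) {
  dat <- dplyr::inner_join(ri, design, by = "sample_id")
  if (nrow(dat) == 0) stop("no ring-index samples match the design", call. = FALSE)
  out <- dat |>
    dplyr::group_by(.data$condition, .data$phase) |>
    dplyr::summarise(
      ri_mean = mean(.data$ri),
      ri_se = if (dplyr::n() >= 2) stats::sd(.data$ri) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n == 0)) stop("empty condition/phase group", call. = FALSE)
  out
}

# Degenerate two-group comparison: both groups constant. Equal means cannot
# be distinguished from no effect (p = 1); different constant means are an
# infinitely strong effect (p = 0, with a warning).
degenerate_t <- function(x, y) {
  if (isTRUE(all.equal(mean(x), mean(y)))) {
    list(t = 0, df = NA_real_, p = 1)
  } else {
    warning("zero-variance groups with different means: p set to 0")
    list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0)
  }
}

#' Two-sample comparison of a lipid metric
#'
#' Welch's t-test by default (pooled-variance Student's t via
#' `pooled = TRUE`); differences are flagged at p < `alpha`.
#'
#' @param x,y Numeric replicate values for the two groups (>= 2 each).
#' @param pooled Use the pooled-variance test instead of Welch.
#' @param alpha Flagging threshold.
#' @return A tibble with `t`, `df`, `p`, `flag`.
#' @export
compare_lipids <- function(x, y, pooled = FALSE, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    res <- degenerate_t(x, y)
  } else {
    ht <- stats::t.test(x, y, var.equal = pooled)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  tibble::tibble(t = res$t, df = res$df, p = res$p, flag = res$p < alpha)
}

#' Stress-versus-optimal tests for ring index and individual GDGTs
#'
#' For every contrast, compares the stress condition with the optimal
#' control at the same phase, for the ring index and each fractional
#' abundance `f_0` .. `f_8`.
#'
#' @param comp Composition tibble from [relative_abundance()].
#' @param design The sample design.
#' @param pooled,alpha Passed to [compare_lipids()].
#' @return A tibble `contrast`, `metric`, `mean_stress`, `mean_optimal`,
#'   `t`, `df`, `p`, `flag`.
#' @export
test_lipid_differences <- function(comp, design = design_samples(),
                                   pooled = FALSE, alpha = 0.05) {
  ri <- ring_index(comp)
  values <- dplyr::inner_join(comp, ri, by = "sample_id") |>
    dplyr::inner_join(design, by = "sample_id")
  metrics <- c("ri", paste0("f_", 0:8))
  contrasts <- design_contrasts()
  purrr::map_dfr(seq_len(nrow(contrasts)), function(k) {
    ph <- contrasts$phase[k]
    stress <- values[values$condition == contrasts$stress[k] & values$phase == ph, ]
    base <- values[values$condition == "optimal" & values$phase == ph, ]
    purrr::map_dfr(metrics, function(m) {
      res <- compare_lipids(stress[[m]], base[[m]], pooled = pooled, alpha = alpha)
      dplyr::bind_cols(
        tibble::tibble(contrast = contrasts$contrast[k], metric = m,
                       mean_stress = mean(stress[[m]]),
                       mean_optimal = mean(base[[m]])),
        res
      )
    })
  })
}
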