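# Transcript-protein concordance. The two omics layers use inverted sign
# conventions (transcripts: negative log2FC = up in stress; proteins:
# positive log2FC = up in stress); this module is where they are
# reconciled, on direction of change rather than raw sign.

#' Curated significant protein abundance changes for S. islandicus stress
#'
#' Ships with the package: the significant protein-level changes observed
#' in *S. islandicus* REY15A under acid and cold stress at each growth
#' phase, with the direction of the corresponding transcript change where
#' one was called (`up` / `down` in stress; `NA` when the transcript did
#' not change). Protein log2FC uses the protein convention (positive =
#' increased under stress).
#'
#' @return A tibble `locus_tag`, `stress`, `phase`, `protein_log2fc`,
#'   `transcript_direction`, `annotation`.
#' @export
load_protein_changes <- function() {
  path <- system.file("extdata", "sislandicus_stress_protein_changes.tsv",
                      package = "sulfostress", mustWork = TRUE)
  read_table(path, "protein_changes")
}

#' Classify transcript-protein concordance
#'
#' Joins significant protein changes with DEG calls on (locus tag, stress,
#' phase) — the same gene at the corresponding growth phase and stress
#' condition. Protein direction is `increased` when the protein log2FC is
#' positive, `decreased` otherwise. Transcript direction comes from the DEG
#' call (`up` / `down` in stress) or is `none` when no DEG was called.
#' Classes: `consistent` for (increased, up) or (decreased, down),
#' `opposite` for the crossed pairs, `no_transcript_change` otherwise.
#'
#' @param protein_changes A tibble with `locus_tag`, `stress`, `phase` and
#'   `protein_log2fc` (significant protein changes only).
#' @param transcript_calls A tibble with `locus_tag`, `stress`, `phase`,
#'   `direction` (`up_in_stress` / `down_in_stress`), e.g. DEG calls.
#' @return A tibble `locus_tag`, `stress`, `phase`, `protein_log2fc`,
#'   `protein_direction`, `transcript_direction`, `class`.
#' @export
concordance_classify <- function(protein_changes, transcript_calls) {
  key <- c("locus_tag", "stress", "phase")
  if (anyDuplicated(protein_changes[, key])) {
    stop("duplicate (locus_tag, stress, phase) rows in protein changes",
         call. = FALSE)
  }
  if (nrow(transcript_calls) > 0 && anyDuplicated(transcript_calls[, key])) {
    stop("duplicate (locus_tag, stress, phase) rows in transcript calls",
         call. = FALSE)
  }
  trans <- transcript_calls |>
    dplyr::mutate(transcript_direction = dplyr::case_when(
      .data$direction == "up_in_stress" ~ "up",
      .data$direction == "down_in_stress" ~ "down",
      TRUE ~ NA_character_
    )) |>
    dplyr::select(dplyr::all_of(key), "transcript_direction")
  protein_changes |>
    dplyr::left_join(trans, by = key) |>
    dplyr::mutate(
      protein_direction = ifelse(.data$protein_log2fc > 0, "increased", "decreased"),
      transcript_direction = ifelse(is.na(.data$transcript_direction),
                                    "none", .data$transcript_direction),
      class = dplyr::case_when(
        transcript_direction == "none" ~ "no_transcript_change",
        (protein_direction == "increased" & transcript_direction == "up") |
          (protein_direction == "decreased" & transcript_direction == "down") ~
          "consistent",
        TRUE ~ "opposite"
      )
    ) |>
    dplyr::select("locus_tag", "stress", "phase", "protein_log2fc",
                  "protein_direction", "transcript_direction", "class")
}

#' Tally concordance classes
#'
#' Counts of consistent, opposite and no-transcript-change records over all
#' significant protein changes and per stress. The three classes always sum
#' to the number of records (asserted).
#'
#' @param records Output of [concordance_classify()].
#' @return A list with `overall` (named counts) and `per_stress` (tibble).
#' @export
concordance_counts <- function(records) {
  tally <- function(d) {
    c(n_consistent = sum(d$class == "consistent"),
      n_opposite = sum(d$class == "opposite"),
      n_no_change = sum(d$class == "no_transcript_change"))
  }
  overall <- tally(records)
  stopifnot(sum(overall) == nrow(records))
  per_stress <- records |>
    dplyr::group_by(.data$stress) |>
    dplyr::summarise(
      n_consistent = sum(.data$class == "consistent"),
      n_opposite = sum(.data$class == "opposite"),
      n_no_change = sum(.data$class == "no_transcript_change"),
      n_records = dplyr::n(),
      .groups = "drop"
    )
  list(overall = as.list(overall), per_stress = per_stress)
}

#' Reference concordance bookkeeping for the curated table
#'
#' Runs the concordance classification on the packaged *S. islandicus*
#' protein-change table, reading transcript directions straight from its
#' `transcript_direction` column, and returns the records together with
#' headline counts: distinct proteins changed per stress and the
#' consistent / opposite / no-change tallies.
#'
#' @return A list with `records`, `counts`, `n_distinct_acid`,
#'   `n_distinct_cold`.
#' @export
reference_concordance <- function() {
  tab <- load_protein_changes()
  transcripts <- tab |>
    dplyr::filter(!is.na(.data$transcript_direction)) |>
    dplyr::mutate(direction = ifelse(.data$transcript_direction == "up",
                                     "up_in_stress", "down_in_stress")) |>
    dplyr::select("locus_tag", "stress", "phase", "direction")
  records <- concordance_classify(
    dplyr::select(tab, "locus_tag", "stress", "phase", "protein_log2fc"),
    transcripts
  )
  list(
    records = records,
    counts = concordance_counts(records),
    n_distinct_acid = dplyr::n_distinct(tab$locus_tag[tab$stress == "acid"]),
    n_distinct_cold = dplyr::n_distinct(tab$locus_tag[tab$stress == "cold"])
  )
}

# ---- End-to-end pipeline ----------------------------------------------------

contrast_meta <- function() {
  dplyr::select(design_contrasts(), "contrast", "stress", "phase")
}

#' Run the full synthetic-to-report pipeline
#'
#' Either simulates a complete input set (`simulate = TRUE`) or reads the
#' input tables from `in_dir` (`design.tsv`, `od_series.tsv`,
#' `gdgt_peaks.tsv`, `counts.tsv`, `protein_quants.tsv`, checked up front),
#' then runs every stage: growth kinetics, lipid compositions and ring
#' indices, replicate QC and the stand-in DE test with DEG calling and the
#' cross-stress Venn partition, the protein Z procedure, and
#' transcript-protein concordance. All stage outputs are written as TSV to
#' `out_dir` alongside `report.json` and `report.md`. Outputs are a pure
#' function of (config, seed); the report's timestamp is segregated in its
#' own field so that content comparison across reruns is stable.
#'
#' @param out_dir Output directory.
#' @param config A [generator_config()]; its seed is used for simulation.
#' @param simulate Generate inputs instead of reading them.
#' @param in_dir Directory with input tables when `simulate = FALSE`.
#' @param lfc_min,deg_padj_max,protein_padj_max,count_floor Thresholds for
#'   DEG and protein calls.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         simulate = TRUE, in_dir = NULL,
                         lfc_min = 1, deg_padj_max = 0.05,
                         protein_padj_max = 0.1, count_floor = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) {
    in_dir <- file.path(out_dir, "inputs")
    simulate_all(config, in_dir)
  } else {
    if (is.null(in_dir)) stop("in_dir required when simulate = FALSE", call. = FALSE)
    needed <- c("design.tsv", "od_series.tsv", "gdgt_peaks.tsv",
                "counts.tsv", "protein_quants.tsv")
    missing <- needed[!file.exists(file.path(in_dir, needed))]
    if (length(missing) > 0) {
      stop("missing input table(s) in ", in_dir, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  design <- read_table(file.path(in_dir, "design.tsv"), "design")
  od <- read_table(file.path(in_dir, "od_series.tsv"), "od_series")
  peaks <- read_table(file.path(in_dir, "gdgt_peaks.tsv"), "gdgt_peaks")
  counts <- read_table(file.path(in_dir, "counts.tsv"), "counts")
  quants <- read_table(file.path(in_dir, "protein_quants.tsv"), "protein_quants")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  growth <- stage("growth", growth_summary(od, design))
  maxima <- od |>
    dplyr::inner_join(design, by = "sample_id") |>
    dplyr::group_by(.data$condition, .data$sample_id) |>
    dplyr::summarise(max_od = max(.data$od), .groups = "drop")
  density_cmp <- stage("growth", compare_max_density(maxima))

  comp <- stage("lipids", relative_abundance(merge_isomers(peaks)))
  ri <- stage("lipids", ring_index(comp))
  ri_summary <- stage("lipids", summarize_condition(ri, design))
  lipid_tests <- stage("lipids", test_lipid_differences(comp, design))

  qc <- stage("degs", replicate_qc(counts, design))
  contrasts <- design_contrasts()
  de <- stage("degs", purrr::map_dfr(seq_len(nrow(contrasts)), function(k) {
    de_test_standin(counts, contrasts[k, ], design = design,
                    count_floor = count_floor)
  }))
  degs <- stage("degs", call_degs(de, lfc_min = lfc_min, padj_max = deg_padj_max))
  venn <- stage("degs", purrr::map_dfr(phases()$phase, function(ph) {
    ctr <- contrasts[contrasts$phase == ph, ]
    venn_partition(
      degs[degs$contrast == ctr$contrast[ctr$stress == "acid"], ],
      degs[degs$contrast == ctr$contrast[ctr$stress == "cold"], ],
      phase = ph
    )
  }))

  pdiff <- stage("protein-diff", diff_protein_abundance(
    quants, design = design, padj_max = protein_padj_max, lfc_min = lfc_min
  ))

  meta <- contrast_meta()
  prot_sig <- pdiff |>
    dplyr::filter(.data$significant) |>
    dplyr::left_join(meta, by = "contrast") |>
    dplyr::transmute(locus_tag = .data$protein_id, stress = .data$stress,
                     phase = .data$phase, protein_log2fc = .data$log2FC)
  trans_calls <- degs |>
    dplyr::left_join(meta, by = "contrast") |>
    dplyr::transmute(locus_tag = .data$gene_id, stress = .data$stress,
                     phase = .data$phase, direction = .data$direction)
  records <- stage("concordance", concordance_classify(prot_sig, trans_calls))
  tallies <- concordance_counts(records)

  coverage <- proteome_coverage(dplyr::n_distinct(quants$protein_id),
                                config$n_proteins)

  write_out <- function(tab, name) {
    readr::write_tsv(tab, file.path(out_dir, name), na = "NA")
  }
  write_out(growth, "growth_summary.tsv")
  write_out(density_cmp$tukey, "max_density_tukey.tsv")
  write_out(comp, "compositions.tsv")
  write_out(ri, "ring_index.tsv")
  write_out(ri_summary, "ring_index_summary.tsv")
  write_out(lipid_tests, "lipid_tests.tsv")
  write_out(qc, "qc.tsv")
  write_out(de, "de_results.tsv")
  write_out(degs, "deg_calls.tsv")
  write_out(venn, "venn.tsv")
  write_out(pdiff, "protein_diff.tsv")
  write_out(records, "concordance.tsv")

  report <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("sulfostress")),
    thresholds = list(lfc_min = lfc_min, deg_padj_max = deg_padj_max,
                      protein_padj_max = protein_padj_max,
                      count_floor = count_floor),
    rows = list(
      od = nrow(od), gdgt = nrow(peaks), genes = nrow(counts),
      protein_quants = nrow(quants),
      degs = nrow(degs),
      significant_proteins = sum(pdiff$significant, na.rm = TRUE)
    ),
    anova_max_density_p = density_cmp$anova_p,
    proteome_coverage = coverage,
    concordance = tallies$overall
  )
  write_report(report, out_dir)
  invisible(report)
}

#' Write the run report
#'
#' Serializes the report as machine-readable JSON plus a short Markdown
#' summary. The generation timestamp lives only in a dedicated top-level
#' field of the JSON (and is omitted from the Markdown), so report content
#' can be compared across reruns.
#'
#' @param report A report list, as assembled by [run_pipeline()].
#' @param out_dir Directory receiving `report.json` and `report.md`.
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  jsonlite::write_json(
    c(report, list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  md <- c(
    "# Pipeline report",
    "",
    paste0("- seed: ", report$seed),
    paste0("- version: ", report$version),
    paste0("- thresholds: |log2FC| >= ", report$thresholds$lfc_min,
           ", DEG padj < ", report$thresholds$deg_padj_max,
           ", protein padj < ", report$thresholds$protein_padj_max),
    paste0("- DEG responses: ", report$rows$degs),
    paste0("- significant protein changes: ", report$rows$significant_proteins),
    paste0("- proteome coverage: ", report$proteome_coverage$label),
    paste0("- concordance: ", report$concordance$n_consistent, " consistent, ",
           report$concordance$n_opposite, " opposite, ",
           report$concordance$n_no_change, " without transcript change")
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
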