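# Seed fan-out: every generator derives its own stream from the global seed
# plus a fixed stage offset, so individual stages are reproducible in
# isolation and adding a stage never perturbs the others.
stage_offsets <- c(truth = 1L, od = 2L, gdgt = 3L, counts = 4L, proteins = 5L)

stage_seed <- function(seed, stage) {
  seed <- as.integer(seed)
  (seed + stage_offsets[[stage]]) %% .Machine$integer.max
}

#' Configuration for the synthetic multi-omics generator
#'
#' Collects every tunable of the simulator with defaults calibrated to the
#' study design being emulated: three conditions (optimal, acid, cold) by
#' two harvest phases by three biological replicates.
#'
#' @param n_genes Number of synthetic genes.
#' @param n_proteins Number of synthetic proteins.
#' @param frac_de Fraction of genes that are differentially expressed in at
#'   least one stress-versus-optimal contrast.
#' @param frac_protein_shift Fraction of proteins carrying a true abundance
#'   shift in one stress condition and phase.
#' @param protein_shift_size Magnitude of the true protein shift in log2
#'   units (at least 1; sign is drawn at random).
#' @param dispersion Negative-binomial dispersion of the count simulator
#'   (variance = mu + dispersion * mu^2). Values below 1e-8 switch to
#'   Poisson sampling.
#' @param dirichlet_concentration Concentration of the Dirichlet draw around
#'   the true lipid composition; larger values give tighter replicates.
#' @param od_noise_sd Additive Gaussian noise on OD600 readings (OD units),
#'   truncated at zero.
#' @param od_interval,od_horizon Sampling interval and total monitored time
#'   for growth curves, in hours.
#' @param total_area Mean total GDGT peak area per sample (arbitrary units).
#' @param spectral_sd Spectrum-level SD of protein log2 ratios (log2 units).
#' @param between_sd Between-biological-replicate SD of protein log2
#'   abundance (log2 units).
#' @param mean_spectra Mean number of quantified spectra per protein and
#'   sample (a shifted Poisson, always at least 1).
#' @param lib_size_jitter Half-width of the uniform library-size factor for
#'   counts (0.3 means factors in \[0.7, 1.3\]).
#' @param seed Global integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000,
                             n_proteins = 500,
                             frac_de = 0.1,
                             frac_protein_shift = 0.05,
                             protein_shift_size = 2,
                             dispersion = 0.05,
                             dirichlet_concentration = 500,
                             od_noise_sd = 0.01,
                             od_interval = 2,
                             od_horizon = 200,
                             total_area = 1e6,
                             spectral_sd = 0.5,
                             between_sd = 0.25,
                             mean_spectra = 5,
                             lib_size_jitter = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_proteins = n_proteins,
    frac_de = frac_de,
    frac_protein_shift = frac_protein_shift,
    protein_shift_size = protein_shift_size,
    dispersion = dispersion,
    dirichlet_concentration = dirichlet_concentration,
    od_noise_sd = od_noise_sd,
    od_interval = od_interval, od_horizon = od_horizon,
    total_area = total_area,
    spectral_sd = spectral_sd, between_sd = between_sd,
    mean_spectra = mean_spectra,
    lib_size_jitter = lib_size_jitter,
    seed = as.integer(seed)
  )
  counts_pos <- c("n_genes", "n_proteins", "total_area", "mean_spectra",
                  "od_interval", "od_horizon")
  for (k in counts_pos) {
    if (cfg[[k]] <= 0) stop("config field '", k, "' must be > 0", call. = FALSE)
  }
  for (k in c("frac_de", "frac_protein_shift")) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      stop("config field '", k, "' must be in [0, 1]", call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  if (cfg$od_noise_sd < 0 || cfg$spectral_sd < 0 || cfg$between_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (abs(cfg$protein_shift_size) < 1)
    stop("protein_shift_size must be at least 1 log2 unit", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' Read generator configuration from a YAML file
#'
#' Any subset of the [generator_config()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(generator_config, vals)
}

# Study-condition growth parameters: specific growth rates derived from the
# observed doubling times (6.8, 9.8, 14.0 h for optimal, acid, cold) and
# carrying capacities from the observed maximum densities (1.48, 0.75, 1.69).
# All cultures start at OD600 = 0.02.
default_growth_truth <- function() {
  tibble::tibble(
    condition = c("optimal", "acid", "cold"),
    td        = c(6.8, 9.8, 14.0),
    mu        = log(2) / c(6.8, 9.8, 14.0),
    K         = c(1.48, 0.75, 1.69),
    od0       = 0.02
  )
}

# Target ring-index values per condition and phase, as observed: mid-log
# 3.65 / 1.59 / 2.83 and early stationary 3.93 / 2.08 / 3.67 for
# optimal / acid / cold.
default_ri_targets <- function() {
  tibble::tibble(
    condition = rep(c("optimal", "acid", "cold"), each = 2),
    phase     = rep(c("mid_log", "early_stationary"), times = 3),
    ri        = c(3.65, 3.93, 1.59, 2.08, 2.83, 3.67)
  )
}

# A composition on rings 0..8 with mean ring number exactly `ri`, built as a
# binomial profile over rings 0..6 (mean = 6p = ri). Rings 7 and 8 get zero
# mass: the organism produces GDGT-0 through -6 under all conditions, with
# GDGT-7 never above 1% and GDGT-8 absent.
composition_for_ri <- function(ri) {
  stopifnot(ri >= 0, ri <= 6)
  f <- c(stats::dbinom(0:6, size = 6, prob = ri / 6), 0, 0)
  names(f) <- paste0("GDGT-", 0:8)
  f
}

gdgt_cols <- function() paste0("GDGT-", 0:8)

#' Generate the ground-truth manifest
#'
#' Draws every latent quantity the downstream generators condition on: the
#' per-condition logistic growth parameters, the true lipid composition and
#' ring index per condition and phase, per-gene true log2 fold changes and
#' DE flags per contrast, and per-protein true log2 abundances per
#' condition and phase with the shifted subset marked.
#'
#' Gene fold-change sign follows the transcript convention used throughout:
#' negative log2FC means increased expression under stress. Protein shifts
#' use the protein convention: positive means increased abundance under
#' stress.
#'
#' @param config A [generator_config()].
#' @return A list of class `truth_manifest`.
#' @export
gen_truth <- function(config = generator_config()) {
  withr::with_seed(stage_seed(config$seed, "truth"), {
    contrasts <- design_contrasts()
    lipids <- default_ri_targets()
    comp <- t(vapply(lipids$ri, composition_for_ri, numeric(9)))
    colnames(comp) <- gdgt_cols()
    lipids <- dplyr::bind_cols(lipids, tibble::as_tibble(comp))

    # Genes: DE genes are assigned a stress scope (acid-only, cold-only or
    # both) and a phase scope (ML-only, ES-only or both); shared-scope genes
    # carry the same effect in every contrast they belong to, so planted
    # "common" responses are recoverable by the Venn partition.
    gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
    n_de <- round(config$frac_de * config$n_genes)
    de_idx <- if (n_de > 0) sample.int(config$n_genes, n_de) else integer(0)
    stress_scope <- sample(c("acid", "cold", "both"), n_de,
                           replace = TRUE, prob = c(0.4, 0.2, 0.4))
    phase_scope <- sample(c("mid_log", "early_stationary", "both"), n_de,
                          replace = TRUE, prob = c(0.2, 0.5, 0.3))
    effect <- sample(c(-1, 1), n_de, replace = TRUE) * stats::runif(n_de, 1, 3)
    lfc <- matrix(0, nrow = config$n_genes, ncol = nrow(contrasts),
                  dimnames = list(gene_id, contrasts$contrast))
    for (k in seq_len(nrow(contrasts))) {
      in_stress <- stress_scope %in% c(contrasts$stress[k], "both")
      in_phase <- phase_scope %in% c(contrasts$phase[k], "both")
      hit <- in_stress & in_phase
      lfc[de_idx[hit], k] <- effect[hit]
    }
    genes <- dplyr::bind_cols(
      tibble::tibble(gene_id = gene_id,
                     base_mean = stats::rlnorm(config$n_genes,
                                               meanlog = log(100), sdlog = 1.2)),
      tibble::as_tibble(lfc)
    )

    # Proteins: log2 abundance relative to the common internal standard is 0
    # at baseline; a subset gets a shift of +/- protein_shift_size in one
    # randomly chosen stress condition and phase.
    protein_id <- sprintf("prot_%04d", seq_len(config$n_proteins))
    cells <- design_samples() |>
      dplyr::distinct(.data$condition, .data$phase)
    abund <- matrix(0, nrow = config$n_proteins, ncol = nrow(cells),
                    dimnames = list(protein_id,
                                    paste(cells$condition, cells$phase, sep = ".")))
    n_shift <- round(config$frac_protein_shift * config$n_proteins)
    shift_idx <- if (n_shift > 0) sample.int(config$n_proteins, n_shift) else integer(0)
    stress_cells <- which(cells$condition != "optimal")
    shift_cell <- sample(stress_cells, n_shift, replace = TRUE)
    shift_sign <- sample(c(-1, 1), n_shift, replace = TRUE)
    for (i in seq_along(shift_idx)) {
      abund[shift_idx[i], shift_cell[i]] <-
        shift_sign[i] * config$protein_shift_size
    }
    proteins <- dplyr::bind_cols(
      tibble::tibble(protein_id = protein_id,
                     shifted = seq_len(config$n_proteins) %in% shift_idx),
      tibble::as_tibble(abund)
    )

    truth <- list(
      seed = config$seed,
      growth = default_growth_truth(),
      lipids = lipids,
      genes = genes,
      proteins = proteins,
      noise = list(
        dispersion = config$dispersion,
        dirichlet_concentration = config$dirichlet_concentration,
        od_noise_sd = config$od_noise_sd,
        spectral_sd = config$spectral_sd,
        between_sd = config$between_sd
      )
    )
    class(truth) <- "truth_manifest"
    truth
  })
}

#' Serialize / restore a truth manifest
#'
#' The manifest round-trips through JSON so recovery tests can be run
#' against archived simulations.
#'
#' @param truth A `truth_manifest`.
#' @param path Output (input) JSON path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns the
#'   manifest.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (tab in c("growth", "lipids", "genes", "proteins")) {
    raw[[tab]] <- tibble::as_tibble(raw[[tab]])
  }
  class(raw) <- "truth_manifest"
  raw
}

logistic_od <- function(t, mu, K, od0) {
  K * od0 * exp(mu * t) / (K + od0 * (exp(mu * t) - 1))
}

#' Generate OD600 growth curves
#'
#' Logistic trajectories `OD(t) = K OD0 e^(mu t) / (K + OD0 (e^(mu t) - 1))`
#' per condition, sampled on a regular grid, with additive Gaussian reading
#' noise truncated at zero. Curves are produced for the three replicates
#' designated for early-stationary harvest in each condition (the cultures
#' monitored over the whole experiment), i.e. nine series.
#'
#' @param config A [generator_config()].
#' @param truth A truth manifest from [gen_truth()].
#' @return A tibble with columns `sample_id`, `time` (h), `od`.
#' @export
gen_od_curves <- function(config = generator_config(), truth = gen_truth(config)) {
  growth <- truth$growth
  if (any(growth$mu <= 0) || any(growth$K <= 0) || any(growth$od0 <= 0)) {
    stop("growth parameters mu, K, od0 must all be > 0", call. = FALSE)
  }
  withr::with_seed(stage_seed(config$seed, "od"), {
    samples <- design_samples() |>
      dplyr::filter(.data$phase == "early_stationary") |>
      dplyr::left_join(growth, by = "condition")
    times <- seq(0, config$od_horizon, by = config$od_interval)
    out <- tidyr::expand_grid(samples, time = times) |>
      dplyr::mutate(
        od_true = logistic_od(.data$time, .data$mu, .data$K, .data$od0),
        od = pmax(0, .data$od_true + stats::rnorm(dplyr::n(), 0, config$od_noise_sd))
      ) |>
      dplyr::select("sample_id", "time", "od")
    out
  })
}

rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) stop("degenerate Dirichlet draw: all-zero alpha", call. = FALSE)
  g / sum(g)
}

#' Generate GDGT peak-area tables
#'
#' Per sample, total peak area is log-normally jittered around
#' `config$total_area` and split over rings 0..8 by a Dirichlet draw centred
#' on the true composition for that condition and phase. A random fraction
#' of the GDGT-3, -4 and -5 mass is then split out into late-eluting isomer
#' columns (`GDGT-3p`, `GDGT-4p`, `GDGT-5p`): up to 10% of the ring's area
#' under acid stress and up to 2% otherwise, mirroring the greater isomer
#' abundance seen at low pH. The split conserves total area exactly.
#'
#' @inheritParams gen_od_curves
#' @return A tibble with `sample_id`, `GDGT-0` .. `GDGT-8`, `GDGT-3p`,
#'   `GDGT-4p`, `GDGT-5p`.
#' @export
gen_gdgt_peaks <- function(config = generator_config(), truth = gen_truth(config)) {
  if (config$dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  }
  withr::with_seed(stage_seed(config$seed, "gdgt"), {
    samples <- design_samples() |>
      dplyr::left_join(truth$lipids, by = c("condition", "phase"))
    areas <- matrix(0, nrow = nrow(samples), ncol = 9,
                    dimnames = list(samples$sample_id, gdgt_cols()))
    totals <- stats::rlnorm(nrow(samples), meanlog = log(config$total_area), sdlog = 0.2)
    for (i in seq_len(nrow(samples))) {
      f_true <- as.numeric(samples[i, gdgt_cols()])
      draw <- rdirichlet1(config$dirichlet_concentration * f_true)
      areas[i, ] <- totals[i] * draw
    }
    iso <- matrix(0, nrow = nrow(samples), ncol = 3,
                  dimnames = list(samples$sample_id,
                                  c("GDGT-3p", "GDGT-4p", "GDGT-5p")))
    iso_max <- ifelse(samples$condition == "acid", 0.10, 0.02)
    for (j in 3:5) {
      share <- stats::runif(nrow(samples), 0, iso_max)
      major <- paste0("GDGT-", j)
      iso[, paste0(major, "p")] <- share * areas[, major]
      areas[, major] <- (1 - share) * areas[, major]
    }
    dplyr::bind_cols(
      tibble::tibble(sample_id = samples$sample_id),
      tibble::as_tibble(areas),
      tibble::as_tibble(iso)
    )
  })
}

#' Generate a synthetic gene count matrix
#'
#' Negative-binomial counts for every gene and sample. Gene baseline means
#' are log-normal; per-library size factors are uniform in
#' `1 +/- lib_size_jitter`. For a gene flagged DE in a contrast, the mean in
#' the stress condition and phase is scaled by `2^(-true log2FC)`, which
#' reproduces the transcript sign convention (negative log2FC = increased
#' expression under stress) end to end.
#'
#' @inheritParams gen_od_curves
#' @return A tibble: `gene_id` plus one integer column per sample (18).
#' @export
gen_counts <- function(config = generator_config(), truth = gen_truth(config)) {
  if (config$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  withr::with_seed(stage_seed(config$seed, "counts"), {
    samples <- design_samples()
    contrasts <- design_contrasts()
    lib <- stats::runif(nrow(samples), 1 - config$lib_size_jitter,
                        1 + config$lib_size_jitter)
    base <- truth$genes$base_mean
    mu <- matrix(base, nrow = length(base), ncol = nrow(samples),
                 dimnames = list(truth$genes$gene_id, samples$sample_id))
    for (k in seq_len(nrow(contrasts))) {
      cols <- samples$condition == contrasts$stress[k] &
        samples$phase == contrasts$phase[k]
      lfc <- truth$genes[[contrasts$contrast[k]]]
      mu[, cols] <- mu[, cols] * 2^(-lfc)
    }
    mu <- sweep(mu, 2, lib, `*`)
    n <- length(mu)
    counts <- if (config$dispersion < 1e-8) {
      stats::rpois(n, lambda = mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = nrow(mu), dimnames = dimnames(mu))
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(counts)),
                     tibble::as_tibble(counts))
  })
}

#' Generate protein quantification tables
#'
#' Emulates isotope-label relative quantification against a common internal
#' standard with two layers of uncertainty. Per protein and sample: the
#' number of quantified spectra is a shifted Poisson (>= 1); the biological
#' replicate carries an offset drawn from `Normal(0, between_sd)`; the
#' reported log2 ratio is the mean of `n_spectra` spectrum-level values
#' distributed `Normal(true + replicate offset, spectral_sd)`; the reported
#' within-sample SE is the sample SD of those spectra over `sqrt(n_spectra)`
#' (when a single spectrum is observed the instrument-level `spectral_sd`
#' is used as the SD estimate).
#'
#' @inheritParams gen_od_curves
#' @return A tibble with `protein_id`, `sample_id`, `log2_ratio`,
#'   `within_se`, `n_spectra`.
#' @export
gen_protein_quants <- function(config = generator_config(), truth = gen_truth(config)) {
  if (config$spectral_sd < 0 || config$between_sd < 0) {
    stop("spectral_sd and between_sd must be >= 0", call. = FALSE)
  }
  withr::with_seed(stage_seed(config$seed, "proteins"), {
    samples <- design_samples()
    cells <- paste(samples$condition, samples$phase, sep = ".")
    cell_cols <- setdiff(names(truth$proteins), c("protein_id", "shifted"))
    abund <- as.matrix(truth$proteins[, cell_cols])
    rownames(abund) <- truth$proteins$protein_id

    grid <- tidyr::expand_grid(protein_id = truth$proteins$protein_id,
                               sample_id = samples$sample_id)
    idx_p <- match(grid$protein_id, rownames(abund))
    idx_s <- match(grid$sample_id, samples$sample_id)
    true_val <- abund[cbind(idx_p, match(cells[idx_s], colnames(abund)))]

    n <- nrow(grid)
    n_spectra <- 1L + stats::rpois(n, lambda = config$mean_spectra - 1)
    rep_eff <- stats::rnorm(n, 0, config$between_sd)
    center <- true_val + rep_eff
    log2_ratio <- stats::rnorm(n, center, config$spectral_sd / sqrt(n_spectra))
    # SD estimate across spectra: sqrt of a scaled chi-square draw, which is
    # exactly the distribution of the sample SD of n normal spectra.
    sd_hat <- ifelse(
      n_spectra >= 2,
      config$spectral_sd *
        sqrt(stats::rchisq(n, df = pmax(n_spectra - 1L, 1L)) / pmax(n_spectra - 1L, 1L)),
      config$spectral_sd
    )
    within_se <- sd_hat / sqrt(n_spectra)
    dplyr::bind_cols(grid, tibble::tibble(
      log2_ratio = log2_ratio,
      within_se = within_se,
      n_spectra = n_spectra
    ))
  })
}

#' Simulate a complete input set
#'
#' Runs every generator and writes `design.tsv`, `od_series.tsv`,
#' `gdgt_peaks.tsv`, `counts.tsv`, `protein_quants.tsv` and `truth.json`
#' into `out_dir`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the truth manifest.
#' @export
simulate_all <- function(config = generator_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- gen_truth(config)
  write_table(design_samples(), file.path(out_dir, "design.tsv"), "design")
  write_table(gen_od_curves(config, truth),
              file.path(out_dir, "od_series.tsv"), "od_series")
  write_table(gen_gdgt_peaks(config, truth),
              file.path(out_dir, "gdgt_peaks.tsv"), "gdgt_peaks")
  write_table(gen_counts(config, truth),
              file.path(out_dir, "counts.tsv"), "counts")
  write_table(gen_protein_quants(config, truth),
              file.path(out_dir, "protein_quants.tsv"), "protein_quants")
  write_truth(truth, file.path(out_dir, "truth.json"))
  invisible(truth)
}
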