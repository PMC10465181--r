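#' @importFrom rlang .data
#' @importFrom stats sd setNames rnorm rpois rnbinom rchisq runif aov
#'   TukeyHSD pnorm pt qnorm t.test cor complete.cases
#' @importFrom utils head
NULL

# ---- Study vocabulary -------------------------------------------------------

#' Experimental growth conditions
#'
#' The three batch-culture conditions of the study design: the optimal
#' growth control (pH 3.4, 76 degrees C), acid stress (pH 2.4, 76 degrees C)
#' and cold stress (pH 3.4, 66 degrees C).
#'
#' @return A tibble with columns `condition`, `pH`, `temperature`.
#' @export
#' @examples
#' conditions()
conditions <- function() {
  tibble::tibble(
    condition   = c("optimal", "acid", "cold"),
    pH          = c(3.4, 2.4, 3.4),
    temperature = c(76, 76, 66)
  )
}

#' Harvest phases
#'
#' Cultures are harvested at two points of the batch growth curve:
#' mid-logarithmic (`mid_log`, short code ML) and early stationary
#' (`early_stationary`, short code ES).
#'
#' @return A tibble with columns `phase`, `code`.
#' @export
phases <- function() {
  tibble::tibble(
    phase = c("mid_log", "early_stationary"),
    code  = c("ML", "ES")
  )
}

phase_code <- function(phase) {
  codes <- setNames(phases()$code, phases()$phase)
  unname(codes[phase])
}

#' Enumerate the full sample design
#'
#' Three conditions crossed with two harvest phases and three biological
#' replicates: 18 samples. Sample identifiers follow the pattern
#' `<condition>_<ML|ES>_r<replicate>`, e.g. `acid_ML_r1`.
#'
#' @return A tibble with columns `sample_id`, `condition`, `phase`,
#'   `replicate` (18 rows).
#' @export
#' @examples
#' nrow(design_samples())  # 18
design_samples <- function() {
  grid <- tidyr::expand_grid(
    condition = conditions()$condition,
    phase     = phases()$phase,
    replicate = 1:3
  )
  dplyr::mutate(
    grid,
    sample_id = paste0(.data$condition, "_", phase_code(.data$phase), "_r", .data$replicate),
    .before   = 1
  )
}

#' Enumerate the stress-versus-optimal contrasts
#'
#' Each stress condition is compared to the optimal control at the same
#' growth phase, giving four contrasts. The baseline is always `optimal`.
#'
#' @return A tibble with columns `contrast`, `stress`, `phase`, `baseline`
#'   (4 rows).
#' @export
design_contrasts <- function() {
  grid <- tidyr::expand_grid(
    stress = c("acid", "cold"),
    phase  = phases()$phase
  )
  dplyr::mutate(
    grid,
    baseline = "optimal",
    contrast = paste0(.data$stress, "_vs_optimal_", phase_code(.data$phase)),
    .before  = 1
  )
}

# ---- Table schemas ----------------------------------------------------------

# Column types are R storage modes; `open` schemas allow extra columns beyond
# the required set (they are preserved verbatim). The counts schema is wide
# (gene_id + one numeric column per sample), so every extra column must be
# numeric.
schema_registry <- function() {
  list(
    design = list(
      required = c(sample_id = "character", condition = "character",
                   phase = "character", replicate = "integer"),
      open = TRUE, extra_type = NULL
    ),
    od_series = list(
      required = c(sample_id = "character", time = "double", od = "double"),
      open = TRUE, extra_type = NULL
    ),
    gdgt_peaks = list(
      required = c(sample_id = "character"),
      open = TRUE, extra_type = "double"
    ),
    counts = list(
      required = c(gene_id = "character"),
      open = TRUE, extra_type = "double"
    ),
    de_results = list(
      required = c(gene_id = "character", contrast = "character",
                   log2FC = "double", pvalue = "double", padj = "double"),
      open = TRUE, extra_type = NULL
    ),
    protein_quants = list(
      required = c(protein_id = "character", sample_id = "character",
                   log2_ratio = "double", within_se = "double",
                   n_spectra = "integer"),
      open = TRUE, extra_type = NULL
    ),
    protein_changes = list(
      required = c(locus_tag = "character", stress = "character",
                   phase = "character", protein_log2fc = "double",
                   transcript_direction = "character"),
      open = TRUE, extra_type = NULL
    )
  )
}

#' Table schemas used by the pipeline
#'
#' Returns the named column specification for one of the pipeline's table
#' kinds. All tables are tab-separated with a header row and `NA` as the
#' only missing-value token.
#'
#' @param kind One of `"design"`, `"od_series"`, `"gdgt_peaks"`, `"counts"`,
#'   `"de_results"`, `"protein_quants"`, `"protein_changes"`.
#' @return A list with `required` (named character vector of column types),
#'   `open` (are extra columns allowed?) and `extra_type`.
#' @export
table_schema <- function(kind) {
  reg <- schema_registry()
  if (!kind %in% names(reg)) {
    stop("unknown table kind '", kind, "'; known kinds: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[kind]]
}

readr_type <- function(type) {
  switch(type,
    character = readr::col_character(),
    double    = readr::col_double(),
    integer   = readr::col_integer(),
    stop("unsupported schema type '", type, "'", call. = FALSE)
  )
}

#' Read a schema-validated TSV table
#'
#' Reads a tab-separated table with a header row, checks that every column
#' required by the schema is present, coerces columns to their declared
#' types, and reports any unparseable cell with its row and column
#' coordinates. Unknown columns and row order are preserved.
#'
#' @param path Path to a TSV file.
#' @param kind Table kind; see [table_schema()].
#' @return A tibble typed per the schema.
#' @export
read_table <- function(path, kind) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  schema <- table_schema(kind)
  header <- names(suppressWarnings(readr::read_tsv(
    path, n_max = 0, show_col_types = FALSE, name_repair = "minimal")))
  missing <- setdiff(names(schema$required), header)
  if (length(missing) > 0) {
    stop("table '", path, "' (", kind, ") is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  types <- lapply(header, function(col) {
    if (col %in% names(schema$required)) {
      readr_type(schema$required[[col]])
    } else if (!is.null(schema$extra_type)) {
      readr_type(schema$extra_type)
    } else {
      readr::col_guess()
    }
  })
  tab <- suppressWarnings(readr::read_tsv(
    path,
    col_types = do.call(readr::cols, setNames(types, header)),
    na = "NA", show_col_types = FALSE, name_repair = "minimal"
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    # readr reports the file line; subtract the header to get the data row
    stop("unparseable cell in '", path, "' at row ", p$row - 1, ", column ",
         header[p$col], " (expected ", p$expected, ", got '", p$actual, "')",
         call. = FALSE)
  }
  tab
}

#' Write a schema-conformant TSV table
#'
#' Writes a tibble as UTF-8 TSV with a header row; missing values are the
#' literal token `NA`. The table is validated against the schema first.
#'
#' @param rows A tibble conforming to the schema.
#' @param path Output path.
#' @param kind Table kind; see [table_schema()].
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, kind) {
  schema <- table_schema(kind)
  missing <- setdiff(names(schema$required), names(rows))
  if (length(missing) > 0) {
    stop("table (", kind, ") is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_tsv(rows, path, na = "NA")
  invisible(path)
}
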