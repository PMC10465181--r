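# Small configs for tests that only exercise one generator stage: the seed
# streams are stage-local, so shrinking unused stages does not change the
# stage under test.
tiny_config <- function(seed, ...) {
  args <- utils::modifyList(list(n_genes = 20, n_proteins = 20, seed = seed),
                            list(...))
  do.call(generator_config, args)
}

# A composition tibble with all mass on the given rings.
comp_row <- function(sample_id, f) {
  stopifnot(length(f) == 9)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id),
    tibble::as_tibble(as.list(setNames(f, paste0("f_", 0:8))))
  )
}

# Independent brute-force ring index: plain loop over ring numbers.
ri_oracle <- function(f) {
  num <- 0
  den <- 0
  for (n in 0:8) {
    num <- num + n * f[n + 1]
    den <- den + f[n + 1]
  }
  num / den
}

# Independent brute-force BH step-up: definition applied literally.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    out[o[i]] <- min(1, min(vals))
  }
  out
}

# Random valid composition on the 9-simplex.
random_comp <- function() {
  x <- stats::runif(9)
  x / sum(x)
}
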