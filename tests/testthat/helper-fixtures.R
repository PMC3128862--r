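sweep_row <- function(query_id, evalue, source_category) {
  tibble::tibble(query_id = query_id, subject_id = "s",
                 percent_identity = 50, evalue = evalue, bit_score = 50,
                 database = "nr", subject_description = "x",
                 source_category = source_category)
}

# top-hit table with categories planted per E-value decade: viral and
# prokaryotic hits fill decades below the cliff, eukaryotic ones above
planted_cliff_tophits <- function(cliff_decade = -4, k_min = -8, k_max = -1,
                                  n_per_decade = 120) {
  rows <- lapply(k_min:k_max, function(k) {
    p_vp <- if (k <= cliff_decade) 0.85 else 0.35
    cat <- ifelse(stats::runif(n_per_decade) < p_vp,
                  sample(c("bacteriophage", "bacteria"), n_per_decade, TRUE),
                  "eukaryote")
    sweep_row(sprintf("q_%d_%03d", k, seq_len(n_per_decade)),
              10^stats::runif(n_per_decade, k, k + 1), cat)
  })
  dplyr::bind_rows(rows)
}

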