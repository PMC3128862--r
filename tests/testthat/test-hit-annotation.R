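hit_row <- function(query_id, evalue, source_category = "bacteria",
                    subject_id = "s1", bit_score = 50, database = "nr",
                    subject_description = "hypothetical protein") {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 percent_identity = 50, evalue = evalue,
                 bit_score = bit_score, database = database,
                 subject_description = subject_description,
                 source_category = source_category)
}

test_that("hit tables round-trip through the TSV dialect with validation", {
  ht <- simulate_hit_table(sprintf("q%d", 1:40), hit_model(hit_rate = 0.5),
                           databases = c("nr", "env_nt"), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(ht, f)
  back <- parse_hit_table(f)
  expect_equal(nrow(back), nrow(ht))
  expect_equal(back$evalue, ht$evalue)

  # empty table with header
  write_hit_table(ht[0, ], f)
  expect_equal(nrow(parse_hit_table(f)), 0)

  # evalue of 0 violates the contract and is rejected with its row number
  bad <- dplyr::bind_rows(hit_row("q1", 1e-5), hit_row("q2", 0))
  write_hit_table(bad, f)
  expect_warning(out <- parse_hit_table(f), "rejecting 1")
  expect_equal(out$query_id, "q1")

  # a missing column is an error naming the column
  readr::write_tsv(ht[, setdiff(hit_table_columns, "bit_score")], f)
  expect_error(parse_hit_table(f), "bit_score")
})

test_that("significance filtering is inclusive, idempotent and monotone", {
  h <- dplyr::bind_rows(hit_row("a", 1e-4), hit_row("b", 1e-3),
                        hit_row("c", 1e-2))
  kept <- filter_significant(h, 1e-3)
  expect_equal(kept$query_id, c("a", "b"))
  expect_identical(filter_significant(kept, 1e-3), kept)
  expect_identical(filter_significant(h, Inf), h)
  expect_equal(nrow(filter_significant(h[0, ], 1e-3)), 0)

  set.seed(5)
  rnd <- hit_row(sprintf("q%d", 1:200), 10^stats::runif(200, -20, 0))
  for (t in 10^c(-12, -8, -3)) {
    s1 <- filter_significant(rnd, t)
    s2 <- filter_significant(rnd, t * 100)
    expect_true(all(s1$query_id %in% s2$query_id))
  }
})

test_that("top hits minimise E-value with score and subject-id tie-breaks", {
  h <- dplyr::bind_rows(
    hit_row("q1", 1e-5, subject_id = "x"),
    hit_row("q1", 1e-8, subject_id = "y"),
    hit_row("q2", 1e-6, bit_score = 80, subject_id = "x"),
    hit_row("q2", 1e-6, bit_score = 95, subject_id = "y"),
    hit_row("q3", 1e-6, subject_id = "b"),
    hit_row("q3", 1e-6, subject_id = "a")
  )
  top <- top_hit_per_query(h)
  expect_equal(nrow(top), 3)
  expect_equal(top$subject_id[top$query_id == "q1"], "y")
  expect_equal(top$subject_id[top$query_id == "q2"], "y")
  expect_equal(top$subject_id[top$query_id == "q3"], "a")
})

test_that("keyword flagging is case-insensitive substring matching", {
  out <- keyword_virus_flag(c(
    "putative major CAPSID protein",
    "hypothetical protein",
    "prophage integrase, phage P2-like",
    "molecular cocktail assembly factor"
  ))
  expect_equal(out$keyword_flag, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$matched_keywords[[1]], "capsid")
  expect_setequal(out$matched_keywords[[3]], c("phage", "integrase"))
  expect_equal(out$matched_keywords[[4]], "tail") # substring, by design
  expect_equal(out$matched_keywords[[2]], character(0))
})

test_that("annotation adds keyword and top-hit columns", {
  h <- dplyr::bind_rows(
    hit_row("q1", 1e-5, subject_description = "phage portal protein"),
    hit_row("q1", 1e-9),
    hit_row("q2", 1e-4)
  )
  ann <- annotate_hits(h)
  expect_equal(sum(ann$is_top_hit), 2)
  expect_true(ann$keyword_flag[1])
  expect_false(ann$keyword_flag[2])
})

test_that("any-hit virus summary separates known viruses from virome matches", {
  rows <- list()
  for (i in 1:114) rows[[length(rows) + 1]] <-
    hit_row(sprintf("p%03d", i), 1e-6, "bacteriophage")
  for (i in 1:7) rows[[length(rows) + 1]] <-
    hit_row(sprintf("e%03d", i), 1e-6, "eukaryotic_virus")
  for (i in 1:22) rows[[length(rows) + 1]] <-
    hit_row(sprintf("m%03d", i), 1e-6, "viral_metagenome")
  # non-viral and non-significant records must not count
  rows[[length(rows) + 1]] <- hit_row("x1", 1e-9, "bacteria")
  rows[[length(rows) + 1]] <- hit_row("x2", 1e-2, "bacteriophage")
  h <- dplyr::bind_rows(rows)

  vs <- any_viral_hit_summary(h, threshold = 1e-3)
  expect_equal(vs$n_any_viral_incl_metagenome, 143)
  expect_equal(vs$n_known_virus, 121)
  expect_equal(vs$n_phage + vs$n_eukaryotic_virus, vs$n_known_virus)
  expect_equal(vs$pct_phage, 94)
  expect_equal(vs$pct_eukaryotic, 6)

  none <- any_viral_hit_summary(hit_row("q", 1e-6, "bacteria"))
  expect_equal(none$n_known_virus, 0)
  expect_true(is.na(none$pct_phage))
})

test_that("top-hit source proportions sum to one including no-hit queries", {
  top <- dplyr::bind_rows(hit_row("q1", 1e-6, "bacteria"),
                          hit_row("q2", 1e-8, "bacteriophage"),
                          hit_row("q3", 1e-1, "eukaryote"))
  d <- top_hit_source_distribution(top, n_queries = 10)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-9)
  expect_equal(d$n[d$category == "no_hit"], 8) # q3 not significant

  allmiss <- top_hit_source_distribution(top[0, ], n_queries = 5)
  expect_equal(allmiss$proportion[allmiss$category == "no_hit"], 1)

  single <- top_hit_source_distribution(hit_row("q", 1e-6, "bacteria"))
  expect_equal(single$proportion[single$category == "bacteria"], 1)
})

test_that("database-group preference uses strictly-better E-values", {
  h <- dplyr::bind_rows(
    hit_row("q1", 1e-9, database = "nr"),                      # only in A
    hit_row("q2", 1e-6, database = "nr"),
    hit_row("q2", 1e-8, database = "env_nt"),                  # B better
    hit_row("q3", 1e-6, database = "nr"),
    hit_row("q3", 1e-6, database = "env_nt")                   # tie: neither
  )
  out <- nr_vs_env_preference(h, "nr", c("env_nt", "gss"), n_queries = 4)
  expect_equal(out$n_a_better, 1)
  expect_equal(out$n_b_better, 1)
  expect_equal(out$pct_a_better, 25)
  expect_error(nr_vs_env_preference(h, "nr", "nr"), "disjoint")
})

test_that("functional tallies bucket unmapped subjects as unknown", {
  v <- dplyr::bind_rows(
    hit_row("q1", 1e-6, "bacteriophage", subject_id = "s_term"),
    hit_row("q2", 1e-6, "bacteriophage", subject_id = "s_cap"),
    hit_row("q3", 1e-6, "bacteriophage", subject_id = "s_mystery"),
    hit_row("q4", 1e-6, "bacteriophage", subject_id = "s_term2")
  )
  fm <- c(s_term = "DNA modification", s_term2 = "DNA modification",
          s_cap = "structure")
  tall <- functional_tally(v, fm)
  expect_equal(tall$n[tall$functional_category == "DNA modification"], 2)
  expect_equal(tall$proportion[tall$functional_category == "DNA modification"], 0.5)
  expect_equal(tall$n[tall$functional_category == "unknown"], 1)

  nomap <- functional_tally(v, c(zzz = "x"))
  expect_equal(nomap$proportion[nomap$functional_category == "unknown"], 1)
  empty <- functional_tally(hit_row("q", 1e-6, "bacteria"), fm)
  expect_equal(nrow(empty), 0)
})
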