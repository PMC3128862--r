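test_that("genome generation honours size classes and is reproducible", {
  gm <- genome_model(list(c(30000, 30000, 1)), n_genomes = 3)
  g <- generate_genomes(gm, seed = 1)
  expect_length(g, 3)
  expect_true(all(nchar(g) == 30000))

  g2 <- generate_genomes(gm, seed = 1)
  expect_identical(g, g2)

  expect_error(genome_model(list(c(1000, 2000, 0.5), c(3000, 4000, 0.4))),
               "sum to 1")
})

test_that("genome class counts fall within the binomial 99% CI of weights", {
  gm <- genome_model(n_genomes = 400)
  g <- generate_genomes(gm, seed = 1)
  k <- attr(g, "size_class")
  w <- gm$size_classes$weight
  for (cls in seq_along(w)) {
    n <- sum(k == cls)
    ci <- stats::qbinom(c(0.005, 0.995), 400, w[cls])
    expect_gte(n, ci[1])
    expect_lte(n, ci[2])
  }
  # lengths actually lie inside their class bounds
  for (cls in seq_along(w)) {
    len <- nchar(g[k == cls])
    expect_true(all(len >= gm$size_classes$min_bp[cls] &
                      len <= gm$size_classes$max_bp[cls]))
  }
})

test_that("shearing produces paired reads under the clone id grammar", {
  gm <- genome_model(list(c(50000, 50000, 1)), n_genomes = 2)
  g <- generate_genomes(gm, seed = 2)
  cm <- clone_model(paired_fraction = 1, duplicate_clone_rate = 0)
  reads <- shear_and_clone(g, cm, 10, seed = 3)
  expect_equal(nrow(reads), 20)
  p <- parse_clone_id(reads$id)
  expect_true(all(p$ok))
  clone <- sub("\\.[FR]$", "", reads$id)
  expect_equal(dplyr::n_distinct(clone), 10)
  per_clone <- table(clone, reads$direction)
  expect_true(all(per_clone == 1))
  # byte-identical reruns
  expect_identical(reads, shear_and_clone(g, cm, 10, seed = 3))
})

test_that("insert lengths respect the size-selection window", {
  gm <- genome_model(list(c(50000, 50000, 1)), n_genomes = 2)
  g <- generate_genomes(gm, seed = 2)
  cm <- clone_model(insert_min_bp = 1400, insert_max_bp = 4000,
                    duplicate_clone_rate = 0)
  reads <- shear_and_clone(g, cm, 50, seed = 4)
  expect_true(all(reads$insert_len >= 1400 & reads$insert_len <= 4000))
})

test_that("a genome shorter than the drawn insert is skipped with a warning", {
  g <- c(tiny = strrep("ACGT", 100)) # 400 bp
  cm <- clone_model(insert_min_bp = 1400, insert_max_bp = 4000)
  w <- testthat::capture_warnings(out <- shear_and_clone(g, cm, 3, seed = 1))
  expect_gte(length(w), 1)
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(out), 0)
})

test_that("duplicate clones are emitted at the stated rate and re-assemble", {
  gm <- genome_model(list(c(150000, 150000, 1)), n_genomes = 10)
  g <- generate_genomes(gm, seed = 5)
  cm <- clone_model(paired_fraction = 0, duplicate_clone_rate = 0.1)
  reads <- shear_and_clone(g, cm, 100, seed = 6)
  n_dup <- sum(reads$is_duplicate)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.1)
  expect_gte(n_dup, ci[1])
  expect_lte(n_dup, ci[2])

  asm <- assemble_greedy(trim_reads(reads))
  # every planted duplicate pair ends up in one contig (>= 95% required;
  # a few extra contigs can arise from genuine coincidental overlaps)
  dup_origins <- unique(reads$origin_clone[reads$is_duplicate])
  recovered <- vapply(dup_origins, function(o) {
    ids <- reads$id[reads$origin_clone == o]
    any(vapply(asm$contigs$member_ids, function(m) all(ids %in% m), TRUE))
  }, TRUE)
  expect_gte(mean(recovered), 0.95)
  expect_gte(nrow(asm$contigs), n_dup)
})

test_that("hit simulation closes the loop with the annotation module", {
  expect_equal(nrow(simulate_hit_table(sprintf("q%d", 1:50),
                                       hit_model(hit_rate = 0), seed = 1)), 0)

  hm <- hit_model(composition = c(bacteriophage = 1), hit_rate = 1)
  ht <- simulate_hit_table(sprintf("q%d", 1:1000), hm, seed = 2)
  top <- top_hit_per_query(ht)
  expect_equal(nrow(top), 1000)
  expect_true(all(top$source_category == "bacteriophage"))
  expect_true(all(grepl(paste(virus_keywords, collapse = "|"),
                        tolower(ht$subject_description))))
  expect_identical(ht, simulate_hit_table(sprintf("q%d", 1:1000), hm, seed = 2))
})

test_that("planted source composition is recovered within the binomial 99% CI", {
  comp <- c(bacteriophage = 0.075 / 0.26, eukaryotic_virus = 0.007 / 0.26,
            mobile_element = 0.006 / 0.26, bacteria = 0.153 / 0.26,
            archaea = 0.005 / 0.26, eukaryote = 0.014 / 0.26)
  hm <- hit_model(composition = comp, hit_rate = 0.26)
  n <- 881
  ht <- simulate_hit_table(sprintf("q%04d", 1:n), hm, seed = 7)
  d <- top_hit_source_distribution(top_hit_per_query(ht), n_queries = n)
  marginal <- c(comp * 0.26, no_hit = 0.74)
  for (cat in names(marginal)) {
    cnt <- sum(d$n[d$category == cat])
    ci <- stats::qbinom(c(0.005, 0.995), n, marginal[[cat]])
    expect_gte(cnt, ci[1])
    expect_lte(cnt, ci[2])
  }
})

test_that("simulated category frequencies pass a chi-square GOF at n = 5000", {
  hm <- hit_model(hit_rate = 1, hits_per_query_mean = 1)
  ht <- simulate_hit_table(sprintf("q%05d", 1:5000), hm, seed = 11)
  obs <- table(factor(ht$source_category, levels = names(hm$composition)))
  p <- stats::chisq.test(obs, p = hm$composition)$p.value
  expect_gt(p, 0.01)
})

test_that("gradient profiles band particles in the peak fractions", {
  gr <- simulate_gradient(n_fractions = 12, peak_fractions = 1:4, seed = 1)
  expect_true(which.max(gr$vlp_per_ml) %in% 1:4)
  d <- fraction_density(gr$mass_g, gr$volume_ml)
  expect_true(all(diff(seq(1.44, 1.55, length.out = 12)) > 0))

  gr0 <- simulate_gradient(n_fractions = 6, density_range = c(1.40, 1.50),
                           peak_fractions = 2, seed = 3, noise_sd = 0)
  expect_equal(fraction_density(gr0$mass_g, gr0$volume_ml),
               seq(1.40, 1.50, length.out = 6))
  expect_true(all(diff(fraction_density(gr0$mass_g, gr0$volume_ml)) > 0))
  expect_identical(gr, simulate_gradient(n_fractions = 12, peak_fractions = 1:4,
                                         seed = 1))
})

test_that("library pairs behave at the sharing extremes", {
  p1 <- generate_library_pair(1, sizes = c(80, 80), seed = 5)
  r_ab <- compare_pair(p1$profile_a, p1$profile_b, p1$hits_b_into_a,
                       p1$hits_a_into_b, length_normalized = FALSE)
  r_ba <- compare_pair(p1$profile_b, p1$profile_a, p1$hits_a_into_b,
                       p1$hits_b_into_a, length_normalized = FALSE)
  # fully shared pools: reciprocal hit percentages approximately equal
  expect_lt(abs(r_ab$param1_pct_ref - r_ba$param1_pct_ref), 10)
  expect_gt(r_ab$param1_pct_ref, 50)

  p0 <- generate_library_pair(0, sizes = c(80, 80), seed = 6)
  expect_lte(nrow(p0$hits_a_into_b), 1)
  expect_lte(nrow(p0$hits_b_into_a), 1)
})
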