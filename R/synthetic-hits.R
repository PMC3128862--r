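#' Closed vocabulary of hit source categories
#'
#' The source categories used to annotate similarity hits: phages,
#' eukaryotic viruses, mobile genetic elements, the three cellular
#' domains, sequences from microbial or viral metagenome surveys, and
#' unknown.
#'
#' @export
source_categories <- c(
  "bacteriophage", "eukaryotic_virus", "mobile_element",
  "bacteria", "archaea", "eukaryote",
  "microbial_metagenome", "viral_metagenome", "unknown"
)

#' Column order of the tabular hit dialect
#' @export
hit_table_columns <- c(
  "query_id", "subject_id", "percent_identity", "evalue",
  "bit_score", "database", "subject_description", "source_category"
)

#' Hit model for the synthetic similarity-search tables
#'
#' A stand-in for database searches: each query independently receives
#' hits with probability `hit_rate`; hit source categories are
#' multinomial with the stated `composition`; E-values are drawn
#' log10-uniform within each category's decade range, which lets the
#' threshold-sweep machinery be exercised across decades without
#' modelling alignment score statistics. The default composition mirrors
#' the top-hit source mix of a coastal virome searched against a
#' comprehensive protein database (conditional on having a hit at all).
#'
#' @param composition named proportions over [source_categories]
#'   (must sum to 1).
#' @param evalue_log10_range named list of `c(lo, hi)` log10 E-value
#'   ranges per category; a single `c(lo, hi)` is recycled to all.
#' @param hit_rate proportion of queries receiving at least one hit.
#' @param hits_per_query_mean mean number of hits for queries that have
#'   any (>= 1).
#' @return an object of class `hit_model`.
#' @export
hit_model <- function(composition = c(bacteriophage = 0.075 / 0.26,
                                      eukaryotic_virus = 0.007 / 0.26,
                                      mobile_element = 0.006 / 0.26,
                                      bacteria = 0.153 / 0.26,
                                      archaea = 0.005 / 0.26,
                                      eukaryote = 0.014 / 0.26),
                      evalue_log10_range = c(-25, -4),
                      hit_rate = 0.26,
                      hits_per_query_mean = 1) {
  if (abs(sum(composition) - 1) > 1e-8) {
    stop("hit_model: composition proportions must sum to 1", call. = FALSE)
  }
  if (!all(names(composition) %in% source_categories)) {
    stop("hit_model: unknown source category in composition", call. = FALSE)
  }
  if (hit_rate < 0 || hit_rate > 1) {
    stop("hit_model: hit_rate must be in [0, 1]", call. = FALSE)
  }
  if (hits_per_query_mean < 1) {
    stop("hit_model: hits_per_query_mean must be >= 1", call. = FALSE)
  }
  if (is.numeric(evalue_log10_range) && length(evalue_log10_range) == 2) {
    evalue_log10_range <- stats::setNames(
      rep(list(evalue_log10_range), length(composition)), names(composition)
    )
  }
  for (r in evalue_log10_range) {
    if (r[1] > r[2]) stop("hit_model: evalue range lo must be <= hi", call. = FALSE)
  }
  structure(list(composition = composition,
                 evalue_log10_range = evalue_log10_range,
                 hit_rate = hit_rate,
                 hits_per_query_mean = hits_per_query_mean),
            class = "hit_model")
}

# descriptions for virus-category hits carry at least one of the eight
# virus keywords; cellular hits get deliberately bland annotations
virus_descriptions <- list(
  bacteriophage = c(
    "phage major capsid protein",
    "prophage integrase, phage P2-like",
    "phage tail fiber protein",
    "portal protein, phage-associated",
    "baseplate assembly protein, Myoviridae phage",
    "terminase large subunit, Siphoviridae phage"
  ),
  eukaryotic_virus = c(
    "Phycodnaviridae major capsid protein",
    "mimivirus capsid protein VP54",
    "nucleocytoplasmic large DNA virus helicase"
  ),
  viral_metagenome = c(
    "uncultured marine virus clone, viral metagenome",
    "environmental virome shotgun sequence"
  )
)

plain_descriptions <- c(
  "hypothetical protein",
  "DNA polymerase III subunit alpha",
  "ABC transporter ATP-binding protein",
  "30S ribosomal protein S12",
  "elongation factor Tu",
  "conserved protein of unknown function"
)

#' Simulate a tabular similarity-hit file
#'
#' Generates one row per query-subject match following the hit-table
#' dialect (see [hit_table_columns]). Virus-category subject
#' descriptions contain virus keywords so the keyword flagging loop can
#' be closed against planted truth.
#'
#' @param reads a read tibble (or a character vector of query ids).
#' @param model a [hit_model()].
#' @param databases database tags to assign uniformly at random.
#' @param seed integer seed.
#' @return a tibble in hit-table dialect order.
#' @export
simulate_hit_table <- function(reads, model, databases = "nr", seed = 1) {
  stopifnot(inherits(model, "hit_model"))
  qids <- if (is.character(reads)) reads else reads$id
  withr::with_seed(sub_seed(seed, 37L), {
    hit <- stats::runif(length(qids)) < model$hit_rate
    qhit <- qids[hit]
    if (length(qhit) == 0) {
      return(tibble::tibble(
        query_id = character(), subject_id = character(),
        percent_identity = numeric(), evalue = numeric(),
        bit_score = numeric(), database = character(),
        subject_description = character(), source_category = character()
      ))
    }
    nhits <- 1L + stats::rpois(length(qhit), model$hits_per_query_mean - 1)
    query_id <- rep(qhit, nhits)
    n <- length(query_id)
    cats <- names(model$composition)
    category <- sample(cats, n, replace = TRUE, prob = model$composition)
    lo <- vapply(model$evalue_log10_range, `[`, 0, 1)[category]
    hi <- vapply(model$evalue_log10_range, `[`, 0, 2)[category]
    evalue <- 10^stats::runif(n, lo, hi)
    descr <- vapply(category, function(cat) {
      pool <- virus_descriptions[[cat]]
      if (is.null(pool)) pool <- plain_descriptions
      sample(pool, 1L)
    }, "")
    tibble::tibble(
      query_id = query_id,
      subject_id = sprintf("sbj_%06d", sample.int(1e6, n, replace = TRUE)),
      percent_identity = round(stats::runif(n, 30, 95), 1),
      evalue = evalue,
      bit_score = round(-1.8 * log10(evalue) + stats::rnorm(n, 0, 2), 1),
      database = sample(databases, n, replace = TRUE),
      subject_description = descr,
      source_category = category
    )
  })
}

#' Simulate a CsCl buoyant-density gradient profile
#'
#' Densities increase monotonically down the gradient (fraction 1 is the
#' top); virus-like particles band in the `peak_fractions`, emulating
#' concentrates whose particles peak at buoyant density ~1.44-1.47 g/ml.
#' Fraction mass is density x volume plus small measurement noise.
#'
#' @param n_fractions number of fractions collected, top first.
#' @param density_range `c(top, bottom)` densities in g/ml.
#' @param peak_fractions indices of fractions holding the particle band.
#' @param seed integer seed.
#' @param volume_ml volume per fraction.
#' @param peak_vlp_per_ml particle concentration in the band.
#' @param background_vlp_per_ml particle concentration elsewhere.
#' @param noise_sd relative s.d. of the mass measurement (0 = exact).
#' @return a tibble with columns `fraction`, `volume_ml`, `mass_g`,
#'   `vlp_per_ml`.
#' @export
simulate_gradient <- function(n_fractions = 12,
                              density_range = c(1.44, 1.55),
                              peak_fractions = 1:4,
                              seed = 1,
                              volume_ml = 0.3,
                              peak_vlp_per_ml = 1.58e11,
                              background_vlp_per_ml = 2e9,
                              noise_sd = 0.0005) {
  stopifnot(n_fractions >= 1)
  withr::with_seed(sub_seed(seed, 41L), {
    density <- seq(density_range[1], density_range[2], length.out = n_fractions)
    conc <- background_vlp_per_ml * stats::runif(n_fractions, 0.8, 1.2)
    conc[peak_fractions] <- peak_vlp_per_ml * stats::runif(length(peak_fractions), 0.9, 1.1)
    mass <- density * volume_ml * (1 + stats::rnorm(n_fractions, 0, noise_sd))
    tibble::tibble(
      fraction = seq_len(n_fractions),
      volume_ml = volume_ml,
      mass_g = mass,
      vlp_per_ml = conc
    )
  })
}

#' Generate a pair of libraries with controlled genome sharing
#'
#' Builds two read libraries whose underlying genome pools share a
#' stated fraction of genomes, then runs [naive_cross_search()] in both
#' directions. This is the test harness for the reciprocal library
#' comparison: hits-per-100 should rise, and reciprocal distance fall,
#' as the shared fraction grows.
#'
#' @param shared_genome_fraction proportion of the genome pool common to
#'   both libraries, in \[0, 1\].
#' @param sizes `c(n_a, n_b)` reads per library.
#' @param read_len_means `c(bp, bp)` mean read lengths.
#' @param seed integer seed.
#' @param n_genomes_each genomes per library pool.
#' @param genome_length length of each pool genome (bp).
#' @param word_size exact-word length for the cross search.
#' @return a list with read tibbles `reads_a`, `reads_b`, profiles
#'   `profile_a`, `profile_b`, and hit tables `hits_a_into_b`,
#'   `hits_b_into_a`.
#' @export
generate_library_pair <- function(shared_genome_fraction,
                                  sizes = c(150, 150),
                                  read_len_means = c(300, 300),
                                  seed = 1,
                                  n_genomes_each = 8,
                                  genome_length = 5000,
                                  word_size = 20) {
  stopifnot(shared_genome_fraction >= 0, shared_genome_fraction <= 1)
  n_shared <- round(shared_genome_fraction * n_genomes_each)
  n_total <- n_shared + 2L * (n_genomes_each - n_shared)
  gm <- genome_model(list(c(genome_length, genome_length, 1)),
                     n_genomes = max(n_total, 1), gc_fraction = 0.45)
  genomes <- generate_genomes(gm, sub_seed(seed, 53L))
  shared_idx <- seq_len(n_shared)
  own_a <- n_shared + seq_len(n_genomes_each - n_shared)
  own_b <- n_shared + (n_genomes_each - n_shared) + seq_len(n_genomes_each - n_shared)
  pool_a <- genomes[c(shared_idx, own_a)]
  pool_b <- genomes[c(shared_idx, own_b)]

  draw_reads <- function(pool, n, len_mean, name, s) {
    withr::with_seed(sub_seed(s, 59L), {
      g <- sample.int(length(pool), n, replace = TRUE)
      len <- pmin(pmax(50L, round(stats::rnorm(n, len_mean, 0.1 * len_mean))),
                  nchar(pool[g]))
      start <- floor(stats::runif(n, 1, nchar(pool[g]) - len + 2))
      tibble::tibble(
        id = sprintf("%s_r%04d", name, seq_len(n)),
        sequence = substr(pool[g], start, start + len - 1L),
        length = len
      )
    })
  }
  reads_a <- draw_reads(pool_a, sizes[1], read_len_means[1], "libA", sub_seed(seed, 1L))
  reads_b <- draw_reads(pool_b, sizes[2], read_len_means[2], "libB", sub_seed(seed, 2L))
  list(
    reads_a = reads_a,
    reads_b = reads_b,
    profile_a = library_profile("libA", nrow(reads_a), mean(reads_a$length)),
    profile_b = library_profile("libB", nrow(reads_b), mean(reads_b$length)),
    hits_a_into_b = naive_cross_search(reads_a, reads_b, word_size = word_size),
    hits_b_into_a = naive_cross_search(reads_b, reads_a, word_size = word_size)
  )
}

#' Write / read a hit table in the package TSV dialect
#'
#' @param hits a hit tibble.
#' @param path file path.
#' @return `path` invisibly (writer); a tibble (reader, see
#'   [parse_hit_table()]).
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, hit_table_columns], path)
  invisible(path)
}

#' Write a gradient profile TSV
#' @param gradient tibble from [simulate_gradient()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gradient_tsv <- function(gradient, path) {
  readr::write_tsv(gradient, path)
  invisible(path)
}

#' Read a gradient profile TSV
#' @param path file path.
#' @return a tibble with columns `fraction`, `volume_ml`, `mass_g`,
#'   `vlp_per_ml`.
#' @export
read_gradient_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
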