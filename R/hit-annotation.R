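#' The eight virus-related keywords
#'
#' Substrings flagged in subject descriptions when screening hits for
#' possible viral origin: "phage" or "virus" (alone or inside a longer
#' word), "capsid", "tail", "integrase", "base plate", "baseplate",
#' "portal".
#'
#' @export
virus_keywords <- c("phage", "virus", "capsid", "tail",
                    "integrase", "base plate", "baseplate", "portal")

viral_categories <- c("bacteriophage", "eukaryotic_virus")
viral_categories_incl_meta <- c(viral_categories, "viral_metagenome")

#' Parse a tabular hit file
#'
#' Reads the package's TSV hit dialect (see [hit_table_columns]).
#' Malformed rows (non-positive or missing E-value, unknown source
#' category, missing query id) are rejected with a warning naming the
#' offending row numbers; a missing column is an error naming the
#' column.
#'
#' @param path path to a TSV hit file.
#' @return a tibble of hit records.
#' @export
parse_hit_table <- function(path) {
  header <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(hit_table_columns, header)
  if (length(missing)) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         percent_identity = readr::col_double(),
                         evalue = readr::col_double(),
                         bit_score = readr::col_double(),
                         .default = readr::col_character()
                       ))
  bad <- is.na(x$query_id) | is.na(x$evalue) | x$evalue <= 0 |
    !(x$source_category %in% source_categories)
  if (any(bad)) {
    warning("rejecting ", sum(bad), " malformed row(s): ",
            paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Keep hits at or below a significance threshold
#'
#' The boundary is inclusive (E <= threshold counts as significant).
#' Idempotent; monotone in the threshold.
#'
#' @param hits hit tibble.
#' @param threshold E-value cut-off.
#' @return filtered hit tibble.
#' @export
filter_significant <- function(hits, threshold = 1e-3) {
  hits[hits$evalue <= threshold, , drop = FALSE]
}

#' Best-scoring hit per query
#'
#' Per query the record with the smallest E-value; ties broken by the
#' largest bit score, then the lexicographically smallest subject id.
#'
#' @param hits hit tibble.
#' @return one record per distinct query.
#' @export
top_hit_per_query <- function(hits) {
  hits |>
    dplyr::arrange(.data$query_id, .data$evalue,
                   dplyr::desc(.data$bit_score), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Flag descriptions containing virus-related keywords
#'
#' Case-insensitive plain substring match against the eight-keyword list
#' (so "cocktail" does match "tail"); flagged records are candidates
#' pending confirmation via the `source_category` column, mirroring
#' manual inspection of automatically flagged hits.
#'
#' @param description character vector of subject descriptions.
#' @return a tibble with `keyword_flag` (logical) and a
#'   `matched_keywords` list-column.
#' @export
keyword_virus_flag <- function(description) {
  if (length(description) == 0) {
    return(tibble::tibble(keyword_flag = logical(), matched_keywords = list()))
  }
  m <- sapply(virus_keywords, function(kw) {
    stringr::str_detect(description, stringr::fixed(kw, ignore_case = TRUE))
  })
  m <- matrix(m, nrow = length(description), ncol = length(virus_keywords))
  tibble::tibble(
    keyword_flag = rowSums(m) > 0,
    matched_keywords = lapply(seq_along(description),
                              function(i) virus_keywords[m[i, ]])
  )
}

#' Annotate a hit table
#'
#' Adds `keyword_flag`, `matched_keywords` and `is_top_hit` columns.
#'
#' @param hits hit tibble.
#' @return annotated hit tibble.
#' @export
annotate_hits <- function(hits) {
  kw <- keyword_virus_flag(hits$subject_description)
  hits$keyword_flag <- kw$keyword_flag
  hits$matched_keywords <- kw$matched_keywords
  top <- top_hit_per_query(hits)
  key <- paste(hits$query_id, hits$subject_id, hits$evalue, hits$bit_score)
  topkey <- paste(top$query_id, top$subject_id, top$evalue, top$bit_score)
  hits$is_top_hit <- key %in% topkey & !duplicated(key)
  hits
}

#' Any-hit virus summary across databases
#'
#' Counts queries with at least one significant hit whose category is
#' viral in the broad sense (bacteriophage, eukaryotic virus, or viral
#' metagenome), then excludes queries whose only viral evidence is a
#' viral-metagenome match to obtain the known-virus count. Known-virus
#' queries are split phage vs eukaryotic virus by their best viral hit;
#' percentages are over the known-virus count, rounded half-up to
#' integers.
#'
#' @param hits hit tibble pooling all databases.
#' @param threshold significance cut-off (inclusive).
#' @return a list of class `virus_summary` with counts
#'   `n_any_viral_incl_metagenome`, `n_known_virus`, `n_phage`,
#'   `n_eukaryotic_virus` and percentages `pct_phage`,
#'   `pct_eukaryotic` (NA when there are no known-virus queries).
#' @export
any_viral_hit_summary <- function(hits, threshold = 1e-3) {
  sig <- filter_significant(hits, threshold)
  anyv <- sig[sig$source_category %in% viral_categories_incl_meta, , drop = FALSE]
  n_any <- dplyr::n_distinct(anyv$query_id)
  known <- sig[sig$source_category %in% viral_categories, , drop = FALSE]
  n_known <- dplyr::n_distinct(known$query_id)
  if (n_known > 0) {
    best <- top_hit_per_query(known)
    n_phage <- sum(best$source_category == "bacteriophage")
    n_euk <- sum(best$source_category == "eukaryotic_virus")
    pct_phage <- round_half_up(100 * n_phage / n_known)
    pct_euk <- round_half_up(100 * n_euk / n_known)
  } else {
    n_phage <- n_euk <- 0L
    pct_phage <- pct_euk <- NA_real_
  }
  structure(list(
    n_any_viral_incl_metagenome = n_any,
    n_known_virus = n_known,
    n_phage = n_phage,
    n_eukaryotic_virus = n_euk,
    pct_phage = pct_phage,
    pct_eukaryotic = pct_euk
  ), class = "virus_summary")
}

#' @export
print.virus_summary <- function(x, ...) {
  cat(sprintf(
    "queries with any viral hit (incl. viral metagenomes): %d\n", x$n_any_viral_incl_metagenome))
  cat(sprintf("queries matching known viruses: %d (%s%% phage, %s%% eukaryotic virus)\n",
              x$n_known_virus, format(x$pct_phage), format(x$pct_eukaryotic)))
  invisible(x)
}

#' Source-category distribution of top hits
#'
#' Proportions of each source category among significant top hits, plus
#' a `no_hit` entry for queries without a significant top hit, so the
#' proportions (over `n_queries`) sum to 1.
#'
#' @param top_hits one record per query (see [top_hit_per_query()]).
#' @param threshold significance cut-off (inclusive).
#' @param n_queries total number of queries in the library, including
#'   those absent from the hit table; defaults to the queries present.
#' @return a tibble with `category`, `n`, `proportion`.
#' @export
top_hit_source_distribution <- function(top_hits, threshold = 1e-3,
                                        n_queries = nrow(top_hits)) {
  sig <- filter_significant(top_hits, threshold)
  tab <- sig |>
    dplyr::count(category = .data$source_category)
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(category = "no_hit", n = n_queries - nrow(sig))
  )
  tab$proportion <- tab$n / n_queries
  tab
}

#' Which database group wins per query
#'
#' For two disjoint groups of databases, the percentage of queries whose
#' best significant hit in group A has a strictly smaller E-value than
#' its best in group B (a query hit only in A counts toward A; equal
#' best E-values count toward neither).
#'
#' @param hits hit tibble.
#' @param group_a,group_b character vectors of database tags.
#' @param threshold significance cut-off (inclusive).
#' @param n_queries denominator for the percentages; defaults to the
#'   distinct queries in `hits`.
#' @return a list with counts `n_a_better`, `n_b_better`, `n_neither`
#'   and `pct_a_better`, `pct_b_better` (one decimal).
#' @export
nr_vs_env_preference <- function(hits, group_a, group_b, threshold = 1e-3,
                                 n_queries = dplyr::n_distinct(hits$query_id)) {
  if (length(intersect(group_a, group_b))) {
    stop("database groups must be disjoint", call. = FALSE)
  }
  sig <- filter_significant(hits, threshold)
  best_in <- function(group) {
    sig[sig$database %in% group, , drop = FALSE] |>
      dplyr::summarise(best = min(.data$evalue), .by = "query_id")
  }
  a <- best_in(group_a)
  b <- best_in(group_b)
  all_q <- union(a$query_id, b$query_id)
  ea <- a$best[match(all_q, a$query_id)]
  eb <- b$best[match(all_q, b$query_id)]
  ea[is.na(ea)] <- Inf
  eb[is.na(eb)] <- Inf
  n_a <- sum(ea < eb)
  n_b <- sum(eb < ea)
  list(
    n_a_better = n_a,
    n_b_better = n_b,
    n_neither = n_queries - n_a - n_b,
    pct_a_better = round_half_up(100 * n_a / n_queries, 1),
    pct_b_better = round_half_up(100 * n_b / n_queries, 1)
  )
}

#' Tally functional categories among virus hits
#'
#' Maps each virus-matching query's best viral hit to a functional
#' category via `function_map`; unmapped subjects fall into an
#' `unknown` bucket.
#'
#' @param virus_hits hit tibble restricted to viral categories (or any
#'   hits; non-viral categories are dropped).
#' @param function_map a named character vector or two-column data frame
#'   (`subject_id`, `functional_category`).
#' @return a tibble with `functional_category`, `n`, `proportion`.
#' @export
functional_tally <- function(virus_hits, function_map) {
  if (is.data.frame(function_map)) {
    function_map <- stats::setNames(function_map$functional_category,
                                    function_map$subject_id)
  }
  v <- virus_hits[virus_hits$source_category %in% viral_categories, , drop = FALSE]
  if (nrow(v) == 0) {
    return(tibble::tibble(functional_category = character(), n = integer(),
                          proportion = numeric()))
  }
  best <- top_hit_per_query(v)
  fc <- unname(function_map[best$subject_id])
  fc[is.na(fc)] <- "unknown"
  out <- tibble::tibble(functional_category = fc) |>
    dplyr::count(.data$functional_category)
  out$proportion <- out$n / sum(out$n)
  out
}
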