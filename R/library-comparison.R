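#' Library metadata profile
#'
#' @param name library name.
#' @param n_sequences number of sequences (un-normalized).
#' @param mean_read_length average read length in bp.
#' @return an object of class `library_profile`.
#' @export
library_profile <- function(name, n_sequences, mean_read_length) {
  if (n_sequences < 1 || mean_read_length <= 0) {
    stop("library_profile: n_sequences >= 1 and mean_read_length > 0 required",
         call. = FALSE)
  }
  structure(list(name = name, n_sequences = n_sequences,
                 mean_read_length = mean_read_length),
            class = "library_profile")
}

#' Read-length-normalized library size
#'
#' Scales a library's sequence count by the ratio of its mean read
#' length to the reference library's mean read length, so that a
#' library with half the reference's mean read length counts as half
#' its sequences. Compensates for the read-length dependence of
#' per-sequence hit rates when comparing libraries sequenced on
#' different platforms.
#'
#' @param n sequence count of the query library.
#' @param mean_len its mean read length (bp).
#' @param ref_mean_len the reference library's mean read length (bp).
#' @return the effective (length-normalized) sequence count.
#' @export
length_normalized_size <- function(n, mean_len, ref_mean_len) {
  if (n <= 0 || mean_len <= 0 || ref_mean_len <= 0) {
    stop("length_normalized_size: all inputs must be positive", call. = FALSE)
  }
  n * mean_len / ref_mean_len
}

#' Pairwise reciprocal library comparison
#'
#' Computes the three pairwise comparison parameters between a reference
#' library and a query library from reciprocal cross-search hit tables.
#' A "hit" is a sequence with at least one match at E-value <=
#' `threshold` (distinct sequences, not match rows). The parameters are:
#' hits into the reference as a percentage of the reference's
#' sequences; hits into the query as a percentage of the query's
#' sequences; and hits into the reference per 100 (optionally
#' length-normalized) query sequences, whose reciprocal is the distance
#' between the libraries. Zero hits give an infinite distance sentinel
#' rather than an error.
#'
#' @param ref,query [library_profile()]s.
#' @param hits_query_into_ref hit table whose queries are the query
#'   library's sequences searched against the reference.
#' @param hits_ref_into_query hit table in the opposite direction.
#' @param threshold significance cut-off (inclusive).
#' @param length_normalized whether to normalize the query library size
#'   by mean read length before computing hits-per-100.
#' @return a one-row tibble of class `comparison_result`.
#' @export
compare_pair <- function(ref, query, hits_query_into_ref, hits_ref_into_query,
                         threshold = 1e-5, length_normalized = TRUE) {
  stopifnot(inherits(ref, "library_profile"), inherits(query, "library_profile"))
  hits_in_ref <- dplyr::n_distinct(
    filter_significant(hits_query_into_ref, threshold)$query_id)
  hits_in_query <- dplyr::n_distinct(
    filter_significant(hits_ref_into_query, threshold)$query_id)
  denom <- if (length_normalized) {
    length_normalized_size(query$n_sequences, query$mean_read_length,
                           ref$mean_read_length)
  } else {
    query$n_sequences
  }
  hp100 <- 100 * hits_in_ref / denom
  tibble::tibble(
    ref_name = ref$name,
    query_name = query$name,
    evalue_threshold = threshold,
    hits_in_ref = hits_in_ref,
    hits_in_query = hits_in_query,
    param1_pct_ref = 100 * hits_in_ref / ref$n_sequences,
    param2_pct_query = 100 * hits_in_query / query$n_sequences,
    hits_per_100_normalized = hp100,
    distance = if (hp100 > 0) 1 / hp100 else Inf,
    length_normalized = length_normalized
  )
}

#' Rank libraries by reciprocal distance
#'
#' Stable ascending sort on distance; infinite-distance entries (no
#' hits at all) sort last and are kept, never dropped.
#'
#' @param results comparison rows sharing one reference (a list of
#'   one-row tibbles or a bound tibble).
#' @return a tibble ordered by ascending distance.
#' @export
rank_libraries <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (dplyr::n_distinct(results$ref_name) > 1) {
    stop("rank_libraries: all results must share the reference library",
         call. = FALSE)
  }
  results[order(results$distance), , drop = FALSE]
}

#' Naive exact-word cross search between two read sets
#'
#' A desk-scale stand-in for a translated similarity search: a query
#' read hits a target read when they share an exact nucleotide word of
#' at least `word_size` bases on either strand. The pseudo-E-value
#' equals 1e-5 at exactly `word_size` matched bases and shrinks by a
#' factor of 4 per additional matched base (floored at 1e-300), so it
#' is monotone in match length and calibrated to the comparison
#' module's default significance threshold. Real search output in the
#' same tabular dialect can be supplied instead wherever this is used.
#'
#' @param query_reads,target_reads read tibbles with `id`, `sequence`.
#' @param word_size exact word length (>= 8).
#' @return a hit tibble in the package dialect, one row per
#'   query-target pair, E-value from the longest shared word.
#' @export
naive_cross_search <- function(query_reads, target_reads, word_size = 20) {
  stopifnot(word_size >= 8)
  w <- as.integer(word_size)
  empty <- tibble::tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), evalue = numeric(), bit_score = numeric(),
    database = character(), subject_description = character(),
    source_category = character()
  )
  if (nrow(query_reads) == 0 || nrow(target_reads) == 0) return(empty)

  words_of <- function(ids, seqs, strand) {
    n <- nchar(seqs)
    keep <- n >= w
    ids <- ids[keep]; seqs <- seqs[keep]; n <- n[keep]
    if (!length(ids)) {
      return(tibble::tibble(id = character(), word = character(),
                            pos = integer(), strand = character()))
    }
    counts <- n - w + 1L
    tibble::tibble(
      id = rep(ids, counts),
      word = unlist(lapply(seqs, function(s) {
        substring(s, 1:(nchar(s) - w + 1L), w:nchar(s))
      })),
      pos = unlist(lapply(counts, seq_len)),
      strand = strand
    )
  }
  tw <- words_of(target_reads$id, target_reads$sequence, "+")
  qw <- dplyr::bind_rows(
    words_of(query_reads$id, query_reads$sequence, "+"),
    words_of(query_reads$id, revcomp(query_reads$sequence), "-")
  )
  m <- dplyr::inner_join(qw, tw, by = "word", suffix = c("_q", "_t"),
                         relationship = "many-to-many")
  if (nrow(m) == 0) return(empty)
  # consecutive seed positions along one diagonal chain into one longer
  # exact match: k consecutive seeds = w + k - 1 matched bases
  best <- m |>
    dplyr::mutate(diag = .data$pos_q - .data$pos_t) |>
    dplyr::arrange(.data$id_q, .data$id_t, .data$strand_q, .data$diag, .data$pos_q) |>
    dplyr::summarise(run = max_consecutive_run(.data$pos_q),
                     .by = c("id_q", "id_t", "strand_q", "diag")) |>
    dplyr::summarise(match_len = w + max(.data$run) - 1L,
                     .by = c("id_q", "id_t"))
  tibble::tibble(
    query_id = best$id_q,
    subject_id = best$id_t,
    percent_identity = 100,
    evalue = pmax(1e-5 * 4^-(best$match_len - w), 1e-300),
    bit_score = 2 * best$match_len,
    database = "cross_search",
    subject_description = sprintf("shared exact word of %d bp", best$match_len),
    source_category = "unknown"
  )
}

# length of the longest run of consecutive integers in a sorted vector
max_consecutive_run <- function(p) {
  if (length(p) == 1L) return(1L)
  r <- rle(diff(p) == 1L)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 1L else max(runs) + 1L
}
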