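#' Default collapse of source categories into broad groups
#'
#' Maps the closed category vocabulary onto the broad groups used in
#' threshold sweeps: virus = bacteriophage + eukaryotic virus,
#' prokaryote = bacteria + archaea, eukaryote stands alone, and
#' everything else (mobile elements, metagenome matches, unknown) is
#' "other". Mobile elements are kept out of the virus group by default
#' because hit-range breakdowns report them separately; pass a modified
#' map to collapse them differently.
#'
#' @return a named character vector category -> group.
#' @export
default_collapse_map <- function() {
  c(bacteriophage = "virus", eukaryotic_virus = "virus",
    bacteria = "prokaryote", archaea = "prokaryote",
    eukaryote = "eukaryote",
    mobile_element = "other", microbial_metagenome = "other",
    viral_metagenome = "other", unknown = "other")
}

sweep_groups <- c("virus", "prokaryote", "eukaryote", "other")

#' Top-hit composition as a function of E-value threshold
#'
#' For each threshold t, the proportions of broad source groups among
#' queries whose top hit has E-value <= t, together with the cumulative
#' fraction of all queries significant at t. The cumulative fraction is
#' non-decreasing as the threshold loosens.
#'
#' @param top_hits one record per query.
#' @param thresholds E-value thresholds; stored loosest-first.
#' @param collapse category -> group map (see [default_collapse_map()]).
#' @param n_queries denominator for the cumulative fraction; defaults to
#'   the number of top-hit records.
#' @return a `threshold_sweep` tibble with columns `threshold`, one per
#'   broad group, `n_hits`, `cumulative_fraction`.
#' @export
sweep_thresholds <- function(top_hits, thresholds = 10^seq(-10, -1),
                             collapse = default_collapse_map(),
                             n_queries = nrow(top_hits)) {
  if (length(thresholds) == 0) stop("empty threshold list", call. = FALSE)
  thresholds <- sort(thresholds, decreasing = TRUE)
  grp <- unname(collapse[top_hits$source_category])
  rows <- lapply(thresholds, function(t) {
    sel <- top_hits$evalue <= t
    n <- sum(sel)
    props <- if (n > 0) {
      tab <- table(factor(grp[sel], levels = sweep_groups))
      as.numeric(tab) / n
    } else {
      rep(NA_real_, length(sweep_groups))
    }
    out <- tibble::tibble(threshold = t, n_hits = n,
                          cumulative_fraction = n / n_queries)
    out[sweep_groups] <- as.list(props)
    out
  })
  out <- dplyr::bind_rows(rows)[, c("threshold", sweep_groups,
                                    "n_hits", "cumulative_fraction")]
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Bin top hits into E-value decades
#'
#' Each hit is assigned to the half-open decade bin \[10^k, 10^(k+1))
#' containing its E-value (so an E-value of exactly 1e-3 falls in the
#' \[1e-3, 1e-2) bin, consistent with the inclusive E <= 0.001
#' significance convention). Hits outside \[10^k_min, 10^(k_max+1))
#' are dropped with a message.
#'
#' @param top_hits one record per query.
#' @param k_min,k_max decade exponents of the lowest and highest bin.
#' @return a `binned_distribution` tibble with `decade` (the bin's lower
#'   exponent k), `category`, `n`, `proportion` (within-bin).
#' @export
bin_by_decade <- function(top_hits, k_min = -10, k_max = -1) {
  stopifnot(k_min < k_max)
  k <- floor(log10(top_hits$evalue) + 1e-12)
  inside <- k >= k_min & k <= k_max
  if (any(!inside)) {
    message(sum(!inside), " hit(s) outside the decade range were dropped")
  }
  x <- tibble::tibble(decade = k[inside],
                      category = top_hits$source_category[inside])
  out <- x |>
    dplyr::count(.data$decade, .data$category) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n), .by = "decade") |>
    dplyr::arrange(.data$decade, .data$category)
  class(out) <- c("binned_distribution", class(out))
  out
}

#' Detect the sharpest drop in viral/prokaryotic hit quality
#'
#' Operationalizes the "sharp decline" seen in hit-composition curves:
#' over decades ordered from stringent to loose, finds the adjacent pair
#' with the maximal decrease in the summed proportion of the stated
#' groups. Ties go to the most stringent pair; a series with no
#' decrease returns `NULL` (none found).
#'
#' @param x a `threshold_sweep` or `binned_distribution`.
#' @param categories broad groups (for sweeps) or raw categories (for
#'   binned distributions) whose summed proportion is scanned.
#' @param collapse category -> group map applied to binned input when
#'   `categories` are broad groups.
#' @return `c(lower, upper)` E-values of the decade pair with the
#'   sharpest drop, or `NULL`.
#' @export
detect_breakpoint <- function(x, categories = c("virus", "prokaryote"),
                              collapse = default_collapse_map()) {
  if (inherits(x, "threshold_sweep")) {
    # a sweep is cumulative: difference it back into per-interval
    # composition so the drop is measured between adjacent intervals,
    # exactly as for decade bins
    ord <- order(x$threshold) # stringent first
    t <- x$threshold[ord]
    present <- intersect(categories, names(x))
    cum_prop <- rowSums(as.data.frame(x)[ord, present, drop = FALSE])
    n <- x$n_hits[ord]
    grp_count <- ifelse(n == 0, 0, cum_prop * n)
    dn <- diff(c(0, n))
    s <- diff(c(0, grp_count)) / ifelse(dn == 0, NA, dn)
    # the pair brackets the interval starts on either side of the drop
    t <- c(t[1] / 10, t[-length(t)])
  } else if (inherits(x, "binned_distribution")) {
    grp <- unname(collapse[x$category])
    sel <- x$category %in% categories | grp %in% categories
    agg <- x |>
      dplyr::mutate(.sel = sel) |>
      dplyr::summarise(s = sum(.data$proportion[.data$.sel]), .by = "decade") |>
      dplyr::arrange(.data$decade)
    t <- 10^agg$decade
    s <- agg$s
  } else {
    stop("detect_breakpoint: expected a threshold_sweep or binned_distribution",
         call. = FALSE)
  }
  if (length(s) < 2) stop("need at least two thresholds/bins", call. = FALSE)
  drops <- s[-length(s)] - s[-1]
  drops[is.na(drops)] <- -Inf
  if (max(drops) <= 0) return(NULL)
  i <- which.max(drops) # which.max takes the first (most stringent) tie
  c(lower = t[i], upper = t[i + 1])
}

#' Ratio of viral hit counts between two search algorithms
#'
#' @param count_a,count_b viral hit counts (e.g. from two translated
#'   search algorithms); `count_b` must be positive.
#' @return `count_a / count_b` rounded half-up to one decimal.
#' @export
viral_hit_ratio <- function(count_a, count_b) {
  if (count_b <= 0) stop("viral_hit_ratio: zero denominator", call. = FALSE)
  round_half_up(count_a / count_b, 1)
}

#' Plot a threshold sweep
#'
#' Line plot of broad-group proportions and the cumulative significant
#' fraction against the E-value threshold (log axis).
#'
#' @param sweep a `threshold_sweep`.
#' @return a ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(as.data.frame(sweep)[, c("threshold", sweep_groups)],
                              -"threshold", names_to = "group",
                              values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$proportion,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = data.frame(threshold = sweep$threshold,
                        proportion = sweep$cumulative_fraction,
                        group = "cumulative significant"),
      linetype = "dashed"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "E-value threshold", y = "proportion of top hits",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
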