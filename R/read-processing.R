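#' Trim reads to a length window
#'
#' Reads longer than `max_len` are truncated at the 3' end (Sanger
#' quality degrades 3'-ward); reads shorter than `min_len` are
#' discarded. The boundary is inclusive: a read of exactly `min_len`
#' is kept. Input order is preserved and the operation is idempotent.
#'
#' @param reads a read tibble with `sequence` (and optionally `length`).
#' @param max_len maximum retained length (bp).
#' @param min_len minimum retained length (bp).
#' @return the trimmed read tibble.
#' @export
trim_reads <- function(reads, max_len = 500, min_len = 100) {
  if (nrow(reads) == 0) return(reads)
  out <- reads
  out$sequence <- substr(out$sequence, 1L, max_len)
  out$length <- nchar(out$sequence)
  out[out$length >= min_len, , drop = FALSE]
}

# ---- greedy overlap assembler ------------------------------------------

# longest qualifying suffix(x)-prefix(y) overlap, ungapped; identity =
# matches / overlap length.  Returns 0 if none qualifies.
best_overlap_len <- function(x, y, min_overlap, min_identity) {
  nx <- nchar(x); ny <- nchar(y)
  if (min(nx, ny) < min_overlap) return(0L)
  xr <- charToRaw(x); yr <- charToRaw(y)
  for (L in seq(min(nx, ny), min_overlap)) {
    mism <- sum(xr[(nx - L + 1L):nx] != yr[1:L])
    if (mism <= floor(L * (1 - min_identity) + 1e-9)) return(L)
  }
  0L
}

# smallest exact-word length guaranteed inside any qualifying overlap:
# m mismatches split an overlap of length L into runs, the longest of
# which is at least ceiling((L - m) / (m + 1)).
prefilter_k <- function(min_overlap, min_identity, max_len) {
  L <- seq(min_overlap, max(min_overlap, max_len))
  m <- floor(L * (1 - min_identity) + 1e-9)
  min(min_overlap, ceiling((L - m) / (m + 1)))
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}


# try the four suffix-prefix configurations between items a and b;
# returns list(len, config) of the longest qualifying overlap or NULL.
# Configs: 1 = a then b, 2 = b then a, 3 = a then revcomp(b),
# 4 = revcomp(b) then a.
best_pair_overlap <- function(a, b, min_overlap, min_identity) {
  rcb <- b$rc
  cand <- list(
    best_overlap_len(a$seq, b$seq, min_overlap, min_identity),
    best_overlap_len(b$seq, a$seq, min_overlap, min_identity),
    best_overlap_len(a$seq, rcb, min_overlap, min_identity),
    best_overlap_len(rcb, a$seq, min_overlap, min_identity)
  )
  L <- vapply(cand, identity, 0L)
  if (max(L) == 0L) return(NULL)
  cfg <- which.max(L) # earliest config wins ties
  list(len = max(L), config = cfg)
}

#' Greedy overlap assembly of trimmed reads
#'
#' Iteratively merges the pair of reads/contigs with the longest
#' suffix-prefix overlap of at least `min_overlap` bases at ungapped
#' identity of at least `min_identity`, considering both strands, until
#' no merge qualifies. Ties on overlap length are broken by the
#' lexicographically smallest member read ids, making the assembly fully
#' deterministic. At a merge the consensus keeps the earlier-assembled
#' item's bases across the overlap (with two sequences per column,
#' majority voting reduces to this tie rule).
#'
#' Candidate pairs are pre-screened by a shared exact k-mer whose length
#' is provably contained in any qualifying overlap (with m mismatches an
#' overlap of length L contains an exact run of at least
#' ceiling((L-m)/(m+1)) bases), so the screen cannot lose a merge.
#'
#' @param reads a trimmed read tibble with `id` and `sequence`.
#' @param min_overlap minimum overlap length (bp).
#' @param min_identity minimum overlap identity in \[0, 1\].
#' @return an object of class `assembly_result`: a list with `contigs`
#'   (tibble: `contig_id`, `member_ids` list-column, `n_members`,
#'   `consensus`, `classification`), `singletons` (read tibble), and
#'   `post_assembly_count`.
#' @export
assemble_greedy <- function(reads, min_overlap = 21, min_identity = 0.98) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1)
  if (anyDuplicated(reads$id)) {
    stop("assemble_greedy: read ids must be unique", call. = FALSE)
  }
  k <- prefilter_k(min_overlap, min_identity, max(nchar(reads$sequence)))

  items <- vector("list", 2L * nrow(reads))
  rc_all <- revcomp(reads$sequence)
  for (i in seq_len(nrow(reads))) {
    items[[i]] <- list(key = i, label = reads$id[i], seq = reads$sequence[i],
                       rc = rc_all[i], members = reads$id[i])
  }
  n_items <- nrow(reads)
  active <- rep(c(TRUE, FALSE), c(n_items, length(items) - n_items))

  word_sets <- lapply(items[seq_len(n_items)], function(it) {
    list(fwd = seq_kmers(it$seq, k), rc = seq_kmers(it$rc, k))
  })
  # candidate pairs = items sharing an exact k-mer (forward-forward or
  # reverse-complement-forward); hash joins keep this near-linear
  fwd_tab <- data.frame(
    word = unlist(lapply(word_sets, `[[`, "fwd"), use.names = FALSE),
    key = rep(seq_len(n_items), vapply(word_sets, function(w) length(w$fwd), 0L))
  )
  rc_tab <- data.frame(
    word = unlist(lapply(word_sets, `[[`, "rc"), use.names = FALSE),
    key = rep(seq_len(n_items), vapply(word_sets, function(w) length(w$rc), 0L))
  )
  shared_ff <- fwd_tab[fwd_tab$word %in% fwd_tab$word[duplicated(fwd_tab$word)], ]
  p1 <- dplyr::inner_join(shared_ff, shared_ff, by = "word",
                          relationship = "many-to-many")
  p2 <- dplyr::inner_join(rc_tab, fwd_tab, by = "word",
                          relationship = "many-to-many")
  pairs <- rbind(
    cbind(pmin(p1$key.x, p1$key.y), pmax(p1$key.x, p1$key.y)),
    cbind(pmin(p2$key.x, p2$key.y), pmax(p2$key.x, p2$key.y))
  )
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])

  merge_items <- function(a, b, cfg, L, key) {
    if (cfg == 1L) { left <- a$seq; right <- b$seq; left_is_a <- TRUE; b_flip <- FALSE }
    if (cfg == 2L) { left <- b$seq; right <- a$seq; left_is_a <- FALSE; b_flip <- FALSE }
    if (cfg == 3L) { left <- a$seq; right <- b$rc; left_is_a <- TRUE; b_flip <- TRUE }
    if (cfg == 4L) { left <- b$rc; right <- a$seq; left_is_a <- FALSE; b_flip <- TRUE }
    nl <- nchar(left); nr <- nchar(right)
    a_earlier <- a$key < b$key
    use_left <- (left_is_a && a_earlier) || (!left_is_a && !a_earlier)
    ovl <- if (use_left) substr(left, nl - L + 1L, nl) else substr(right, 1L, L)
    cons <- paste0(substr(left, 1L, nl - L), ovl, substr(right, L + 1L, nr))
    list(key = key, label = min(a$label, b$label), seq = cons,
         rc = revcomp(cons), members = c(a$members, b$members))
  }

  # an overlap between two items never changes while both stay unmerged,
  # so each candidate pair is scored exactly once
  score_pairs <- function(pm) {
    rows <- lapply(seq_len(nrow(pm)), function(r) {
      i <- pm[r, 1]; j <- pm[r, 2]
      ov <- best_pair_overlap(items[[i]], items[[j]], min_overlap, min_identity)
      if (is.null(ov)) return(NULL)
      lab <- sort(c(items[[i]]$label, items[[j]]$label))
      data.frame(i = i, j = j, len = ov$len, config = ov$config,
                 lab1 = lab[1], lab2 = lab[2])
    })
    do.call(rbind, rows)
  }
  cand <- if (nrow(pairs)) score_pairs(pairs) else NULL

  repeat {
    if (is.null(cand) || nrow(cand) == 0) break
    cand <- cand[active[cand$i] & active[cand$j], , drop = FALSE]
    if (nrow(cand) == 0) break
    ord <- order(-cand$len, cand$lab1, cand$lab2)
    best <- cand[ord[1], ]
    n_items <- n_items + 1L
    if (n_items > length(items)) items <- c(items, vector("list", n_items))
    new <- merge_items(items[[best$i]], items[[best$j]], best$config, best$len, n_items)
    items[[n_items]] <- new
    active[best$i] <- FALSE
    active[best$j] <- FALSE
    active[n_items] <- TRUE
    word_sets[[n_items]] <- list(fwd = seq_kmers(new$seq, k), rc = seq_kmers(new$rc, k))
    # partners of the merged item: rescreen word sets against remaining actives
    others <- setdiff(which(active), n_items)
    if (length(others)) {
      nf <- word_sets[[n_items]]$fwd
      nr <- word_sets[[n_items]]$rc
      p <- others[vapply(others, function(o) {
        any(nf %in% word_sets[[o]]$fwd) || any(nr %in% word_sets[[o]]$fwd)
      }, TRUE)]
      if (length(p)) {
        extra <- score_pairs(cbind(pmin(n_items, p), pmax(n_items, p)))
        if (!is.null(extra)) cand <- rbind(cand, extra)
      }
    }
  }

  fin <- Filter(Negate(is.null), items[which(active)])
  multi <- Filter(function(it) length(it$members) > 1L, fin)
  multi <- multi[order(vapply(multi, `[[`, "", "label"))]
  contigs <- tibble::tibble(
    contig_id = sprintf("contig_%03d", seq_along(multi)),
    member_ids = lapply(multi, `[[`, "members"),
    n_members = vapply(multi, function(it) length(it$members), 0L),
    consensus = vapply(multi, `[[`, "", "seq"),
    classification = NA_character_
  )
  single_ids <- unlist(lapply(Filter(function(it) length(it$members) == 1L, fin),
                              `[[`, "members"))
  singletons <- reads[reads$id %in% single_ids, , drop = FALSE]
  structure(list(contigs = contigs, singletons = singletons,
                 post_assembly_count = nrow(contigs) + nrow(singletons),
                 n_input_reads = nrow(reads)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("Assembly of %d reads: %d contigs + %d singletons = %d sequences\n",
              x$n_input_reads, nrow(x$contigs), nrow(x$singletons),
              x$post_assembly_count))
  invisible(x)
}

#' Classify contigs by the plate geometry of their members
#'
#' A contig is `same_clone` when all members share library, plate and
#' well (forward and reverse reads of one clone); `adjacent_well_suspect`
#' when members share library and plate and their wells are at Manhattan
#' distance 1 (possible well-to-well carry-over); otherwise
#' `independent`. Member ids that do not parse under the clone-id
#' grammar give classification `unknown` with a warning.
#'
#' @param contigs the `contigs` tibble of an [assemble_greedy()] result
#'   (or any tibble with a `member_ids` list-column).
#' @return the tibble with `classification` filled in.
#' @export
classify_contigs <- function(contigs) {
  if (nrow(contigs) == 0) return(contigs)
  contigs$classification <- vapply(contigs$member_ids, function(ids) {
    p <- parse_clone_id(ids)
    if (!all(p$ok)) {
      warning("unparseable member id(s): ",
              paste(ids[!p$ok], collapse = ", "), call. = FALSE)
      return("unknown")
    }
    same_lib_plate <- length(unique(p$library)) == 1 && length(unique(p$plate)) == 1
    same_well <- same_lib_plate && length(unique(paste(p$well_row, p$well_col))) == 1
    if (same_well) return("same_clone")
    if (same_lib_plate) {
      r <- match(p$well_row, LETTERS)
      c <- p$well_col
      d <- outer(r, r, function(x, y) abs(x - y)) + outer(c, c, function(x, y) abs(x - y))
      if (max(d) == 1) return("adjacent_well_suspect")
    }
    "independent"
  }, "")
  contigs
}

#' Post-assembly sequence count
#'
#' The number of sequences remaining after assembly: input reads minus
#' reads absorbed into contigs, plus one consensus per contig.
#'
#' @param n_reads number of input reads.
#' @param contigs contig tibble with `n_members`.
#' @return integer count.
#' @export
post_assembly_count <- function(n_reads, contigs) {
  out <- n_reads - sum(contigs$n_members) + nrow(contigs)
  if (out < 0) stop("post_assembly_count: more contig members than reads", call. = FALSE)
  out
}

#' Percentage of reads in non-same-clone contigs
#'
#' Reads absorbed into contigs whose members are *not* simply the
#' forward and reverse read of one clone, expressed as a percentage of
#' all input reads (one decimal, round half-up). These are the candidate
#' "legitimate" contigs formed between independently picked clones.
#'
#' @param n_reads number of input reads.
#' @param contigs classified contig tibble.
#' @return percentage at one decimal.
#' @export
interclone_read_fraction <- function(n_reads, contigs) {
  if (n_reads == 0) stop("interclone_read_fraction: n_reads is zero", call. = FALSE)
  n <- sum(contigs$n_members[contigs$classification != "same_clone"])
  round_half_up(100 * n / n_reads, 1)
}

#' Write a contig report TSV
#'
#' @param contigs classified contig tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contig_report <- function(contigs, path) {
  out <- tibble::tibble(
    contig_id = contigs$contig_id,
    members = vapply(contigs$member_ids, paste, "", collapse = ","),
    n_members = contigs$n_members,
    classification = contigs$classification,
    consensus_length = nchar(contigs$consensus)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
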