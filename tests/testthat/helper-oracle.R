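# Brute-force assembly oracle: exhaustive all-pairs suffix-prefix scan
# with no k-mer prescreening, operating on character vectors. Shares the
# greedy policy (longest overlap first, lexicographic label tie-break,
# fixed configuration preference) but none of the implementation.

rc_chr <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

oracle_overlap <- function(xa, ya, min_ov, min_id) {
  nx <- length(xa)
  ny <- length(ya)
  lim <- min(nx, ny)
  if (lim < min_ov) return(0L)
  best <- 0L
  for (L in min_ov:lim) {
    mism <- sum(xa[(nx - L + 1):nx] != ya[1:L])
    if (mism <= floor(L * (1 - min_id) + 1e-9)) best <- L
  }
  best
}

oracle_assemble <- function(reads, min_ov = 21, min_id = 0.98) {
  items <- lapply(seq_len(nrow(reads)), function(i) {
    s <- reads$sequence[i]
    list(key = i, label = reads$id[i],
         f = strsplit(s, "")[[1]],
         r = strsplit(rc_chr(s), "")[[1]],
         members = reads$id[i])
  })
  nxt <- length(items)
  repeat {
    best <- NULL
    n <- length(items)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        a <- items[[i]]
        b <- items[[j]]
        lens <- c(
          oracle_overlap(a$f, b$f, min_ov, min_id),
          oracle_overlap(b$f, a$f, min_ov, min_id),
          oracle_overlap(a$f, b$r, min_ov, min_id),
          oracle_overlap(b$r, a$f, min_ov, min_id)
        )
        if (max(lens) == 0) next
        lab <- sort(c(a$label, b$label))
        cand <- list(i = i, j = j, len = max(lens), config = which.max(lens),
                     lab = lab)
        if (is.null(best) || cand$len > best$len ||
            (cand$len == best$len &&
             (cand$lab[1] < best$lab[1] ||
              (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    a <- items[[best$i]]
    b <- items[[best$j]]
    cfg <- best$config
    L <- best$len
    if (cfg == 1) { left <- a$f; right <- b$f; left_is_a <- TRUE }
    if (cfg == 2) { left <- b$f; right <- a$f; left_is_a <- FALSE }
    if (cfg == 3) { left <- a$f; right <- b$r; left_is_a <- TRUE }
    if (cfg == 4) { left <- b$r; right <- a$f; left_is_a <- FALSE }
    nl <- length(left)
    use_left <- (left_is_a && a$key < b$key) || (!left_is_a && a$key > b$key)
    ovl <- if (use_left) left[(nl - L + 1):nl] else right[1:L]
    cons <- c(left[seq_len(nl - L)], ovl, right[-seq_len(L)])
    nxt <- nxt + 1L
    merged <- list(key = nxt, label = min(a$label, b$label),
                   f = cons, r = rev(chartr("ACGTN", "TGCAN", cons)),
                   members = c(a$members, b$members))
    items <- c(items[-c(best$i, best$j)], list(merged))
  }
  lapply(items, `[[`, "members")
}

canon_partition <- function(members_list) {
  s <- lapply(members_list, sort)
  s[order(vapply(s, paste, "", collapse = "|"))]
}

assembly_partition <- function(asm) {
  canon_partition(c(asm$contigs$member_ids, as.list(asm$singletons$id)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small read set mixing genome-derived (hence overlapping) and purely
# random reads, some reverse-complemented
random_read_instance <- function(n_reads, genome_len = 500,
                                 read_len = c(40, 90)) {
  genome <- random_dna(genome_len)
  seqs <- vapply(seq_len(n_reads), function(i) {
    len <- sample(read_len[1]:read_len[2], 1)
    if (stats::runif(1) < 0.6) {
      start <- sample(genome_len - len + 1, 1)
      s <- substr(genome, start, start + len - 1)
    } else {
      s <- random_dna(len)
    }
    if (stats::runif(1) < 0.3) s <- rc_chr(s)
    s
  }, "")
  tibble::tibble(id = sprintf("r%02d", seq_len(n_reads)),
                 sequence = seqs, length = nchar(seqs))
}
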