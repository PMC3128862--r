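#' Genome model for the synthetic virus community
#'
#' Describes a mixture of viral genome size classes. The default mirrors
#' the four major size classes seen on pulsed-field gels of marine
#' virus-like particles (30-45 kb, 60-80 kb, ~125 kb, and >146 kb); the
#' class weights are not published, so the defaults put most mass on the
#' two smaller classes, as expected for tailed-phage-dominated plankton.
#'
#' @param size_classes list of `c(min_bp, max_bp, weight)` triples;
#'   weights must sum to 1.
#' @param n_genomes number of genomes to draw.
#' @param gc_fraction GC content of the simulated genomes, in \[0, 1\].
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(size_classes = list(
                           c(30000, 45000, 0.40),
                           c(60000, 80000, 0.30),
                           c(125000, 125000, 0.15),
                           c(146000, 200000, 0.15)
                         ),
                         n_genomes = 40,
                         gc_fraction = 0.45) {
  cls <- do.call(rbind, lapply(size_classes, function(x) {
    stopifnot(length(x) == 3)
    x
  }))
  cls <- tibble::tibble(min_bp = cls[, 1], max_bp = cls[, 2], weight = cls[, 3])
  if (abs(sum(cls$weight) - 1) > 1e-8) {
    stop("genome_model: size-class weights must sum to 1", call. = FALSE)
  }
  if (any(cls$min_bp > cls$max_bp) || any(cls$weight < 0)) {
    stop("genome_model: invalid size class (min > max or negative weight)", call. = FALSE)
  }
  if (n_genomes < 1) stop("genome_model: n_genomes must be >= 1", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("genome_model: gc_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(size_classes = cls, n_genomes = n_genomes,
                 gc_fraction = gc_fraction),
            class = "genome_model")
}

#' Generate a set of synthetic viral genomes
#'
#' Each genome's length is drawn by first choosing a size class by weight
#' and then sampling uniformly within the class. Bases are i.i.d. at the
#' model's GC fraction (no repeat structure is simulated; the genomes
#' exist to be sheared into clones and to carry exact overlaps).
#'
#' @param model a [genome_model()].
#' @param seed integer seed; the same model and seed give byte-identical
#'   output.
#' @return a named character vector of genome sequences, with the drawn
#'   size class attached as attribute `"size_class"`.
#' @export
generate_genomes <- function(model, seed) {
  stopifnot(inherits(model, "genome_model"))
  withr::with_seed(sub_seed(seed, 11L), {
    cls <- model$size_classes
    k <- sample.int(nrow(cls), model$n_genomes, replace = TRUE, prob = cls$weight)
    len <- floor(stats::runif(model$n_genomes, cls$min_bp[k], cls$max_bp[k] + 1))
    gc <- model$gc_fraction
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(len, function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, "")
    names(seqs) <- sprintf("genome_%03d", seq_along(seqs))
    attr(seqs, "size_class") <- k
    seqs
  })
}

#' Clone model for shearing and end-sequencing
#'
#' Parameters of the simulated shotgun cloning step: sheared inserts are
#' size-selected to `insert_min_bp`..`insert_max_bp` (1.4-4 kb by
#' default, the gel slice excised in the study design this emulates) and
#' end-sequenced from one or both ends. `duplicate_clone_rate` re-emits a
#' clone's insert under a fresh well id, planting the kind of
#' "legitimate" inter-clone contig an assembler should recover.
#'
#' @param insert_min_bp,insert_max_bp insert size-selection window (bp).
#' @param read_len_mean,read_len_sd Sanger read length distribution (bp).
#' @param paired_fraction proportion of clones sequenced from both ends.
#' @param duplicate_clone_rate proportion of clones re-emitted under a
#'   new well id.
#' @return an object of class `clone_model`.
#' @export
clone_model <- function(insert_min_bp = 1400, insert_max_bp = 4000,
                        read_len_mean = 440, read_len_sd = 60,
                        paired_fraction = 1, duplicate_clone_rate = 0.01) {
  if (insert_min_bp > insert_max_bp) {
    stop("clone_model: insert_min_bp must be <= insert_max_bp", call. = FALSE)
  }
  for (p in c(paired_fraction, duplicate_clone_rate)) {
    if (p < 0 || p > 1) stop("clone_model: proportions must be in [0, 1]", call. = FALSE)
  }
  if (insert_min_bp < 50) {
    stop("clone_model: insert_min_bp below the read length floor", call. = FALSE)
  }
  structure(list(insert_min_bp = insert_min_bp, insert_max_bp = insert_max_bp,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 paired_fraction = paired_fraction,
                 duplicate_clone_rate = duplicate_clone_rate),
            class = "clone_model")
}

# map a running clone counter onto 96-well plate coordinates
well_position <- function(i) {
  w <- (i - 1L) %% 96L
  list(plate = (i - 1L) %/% 96L + 1L,
       row = LETTERS[w %/% 12L + 1L],
       col = w %% 12L + 1L)
}

#' Shear genomes into clones and emit end reads
#'
#' Each clone is a uniform-random insert from a uniformly chosen genome.
#' The forward read covers the 5' end of the insert; for paired clones
#' the reverse read is the reverse complement of the 3' end. Clone ids
#' encode library, plate, well and direction (see [format_clone_id()]).
#' A `duplicate_clone_rate` fraction of clones is re-emitted with the
#' identical insert under the next free well id.
#'
#' @param genomes named character vector from [generate_genomes()].
#' @param model a [clone_model()].
#' @param n_clones number of primary clones to draw.
#' @param seed integer seed.
#' @param library library name used in read ids.
#' @return a tibble of reads with columns `id`, `library`, `plate`,
#'   `well_row`, `well_col`, `direction`, `sequence`, `length`, and the
#'   generator-bookkeeping columns `insert_len`, `origin_clone` (primary
#'   clone index a read's insert came from) and `is_duplicate`.
#' @export
shear_and_clone <- function(genomes, model, n_clones, seed, library = "MBv") {
  stopifnot(inherits(model, "clone_model"), n_clones >= 1)
  glen <- nchar(genomes)
  withr::with_seed(sub_seed(seed, 23L), {
    rows <- list()
    counter <- 0L
    emit <- function(insert, origin, paired, is_dup, rl_f, rl_r) {
      counter <<- counter + 1L
      pos <- well_position(counter)
      out <- list()
      fseq <- substr(insert, 1L, min(rl_f, nchar(insert)))
      out[[1]] <- tibble::tibble(
        id = format_clone_id(library, pos$plate, pos$row, pos$col, "F"),
        library = library, plate = pos$plate, well_row = pos$row,
        well_col = pos$col, direction = "F", sequence = fseq,
        length = nchar(fseq), insert_len = nchar(insert),
        origin_clone = origin, is_duplicate = is_dup
      )
      if (paired) {
        n <- nchar(insert)
        rseq <- revcomp(substr(insert, max(1L, n - rl_r + 1L), n))
        out[[2]] <- tibble::tibble(
          id = format_clone_id(library, pos$plate, pos$row, pos$col, "R"),
          library = library, plate = pos$plate, well_row = pos$row,
          well_col = pos$col, direction = "R", sequence = rseq,
          length = nchar(rseq), insert_len = nchar(insert),
          origin_clone = origin, is_duplicate = is_dup
        )
      }
      out
    }
    for (i in seq_len(n_clones)) {
      g <- sample.int(length(genomes), 1L)
      ilen <- floor(stats::runif(1, model$insert_min_bp, model$insert_max_bp + 1))
      if (glen[g] < ilen) {
        warning(sprintf("genome %s shorter than drawn insert (%d bp); clone skipped",
                        names(genomes)[g], ilen), call. = FALSE)
        next
      }
      start <- floor(stats::runif(1, 1, glen[g] - ilen + 2))
      insert <- substr(genomes[[g]], start, start + ilen - 1L)
      paired <- stats::runif(1) < model$paired_fraction
      rl_f <- max(50L, round(stats::rnorm(1, model$read_len_mean, model$read_len_sd)))
      rl_r <- max(50L, round(stats::rnorm(1, model$read_len_mean, model$read_len_sd)))
      rows <- c(rows, emit(insert, i, paired, FALSE, rl_f, rl_r))
      if (stats::runif(1) < model$duplicate_clone_rate) {
        rows <- c(rows, emit(insert, i, paired, TRUE, rl_f, rl_r))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a library with planted assembly structure
#'
#' Builds a read set of known assembly outcome: `n_same_clone_pairs`
#' clones whose forward and reverse reads overlap across a short
#' insert (assembling into same-clone contigs), `n_duplicate_pairs`
#' clone inserts emitted twice under adjacent well ids (assembling into
#' different-name contigs), and singleton reads drawn from disjoint
#' genome windows so that no other overlap of `min_overlap` bases or
#' more exists by construction. The defaults reproduce the bookkeeping
#' of a 907-read Sanger library collapsing to 881 sequences via 26
#' two-member contigs.
#'
#' @param n_reads total number of reads.
#' @param n_same_clone_pairs forward/reverse read pairs of one clone.
#' @param n_duplicate_pairs duplicated inserts under different wells.
#' @param seed integer seed.
#' @param read_len read length before trimming (bp).
#' @param pair_insert_len insert length of the short paired clones (must
#'   be < 2 * `read_len` so the end reads overlap).
#' @param library library name for the clone ids.
#' @return a read tibble; the planted role of each read is in the
#'   `planted` column (`"single"`, `"same_clone"`, `"duplicate"`).
#' @export
generate_planted_library <- function(n_reads = 907, n_same_clone_pairs = 20,
                                     n_duplicate_pairs = 6, seed = 1,
                                     read_len = 450, pair_insert_len = 700,
                                     library = "MBv") {
  n_pair_reads <- 2L * (n_same_clone_pairs + n_duplicate_pairs)
  n_single <- n_reads - n_pair_reads
  stopifnot(n_single >= 0, pair_insert_len < 2 * read_len)
  withr::with_seed(sub_seed(seed, 67L), {
    gm <- genome_model(n_genomes = 40)
    genomes <- generate_genomes(gm, sub_seed(seed, 68L))
    pool <- paste(genomes, collapse = "")
    # disjoint, gap-separated windows guarantee no cross-window overlap
    slot_len <- max(read_len, pair_insert_len) + 50L
    n_slots <- n_single + n_same_clone_pairs + n_duplicate_pairs
    stopifnot(n_slots * slot_len <= nchar(pool))
    starts <- sample((seq_len(n_slots) - 1L) * slot_len + 1L)
    rows <- list()
    counter <- 0L
    next_well <- function() {
      counter <<- counter + 1L
      well_position(counter)
    }
    read_row <- function(pos, dir, seqs, planted) {
      tibble::tibble(
        id = format_clone_id(library, pos$plate, pos$row, pos$col, dir),
        library = library, plate = pos$plate, well_row = pos$row,
        well_col = pos$col, direction = dir, sequence = seqs,
        length = nchar(seqs), planted = planted
      )
    }
    s <- 0L
    for (i in seq_len(n_same_clone_pairs)) {
      s <- s + 1L
      insert <- substr(pool, starts[s], starts[s] + pair_insert_len - 1L)
      pos <- next_well()
      rows <- c(rows, list(
        read_row(pos, "F", substr(insert, 1L, read_len), "same_clone"),
        read_row(pos, "R",
                 revcomp(substr(insert, pair_insert_len - read_len + 1L,
                                pair_insert_len)), "same_clone")
      ))
    }
    for (i in seq_len(n_duplicate_pairs)) {
      s <- s + 1L
      rd <- substr(pool, starts[s], starts[s] + read_len - 1L)
      pos1 <- next_well()
      pos2 <- next_well() # the next well on the plate: adjacent by design
      rows <- c(rows, list(
        read_row(pos1, "F", rd, "duplicate"),
        read_row(pos2, "F", rd, "duplicate")
      ))
    }
    for (i in seq_len(n_single)) {
      s <- s + 1L
      rd <- substr(pool, starts[s], starts[s] + read_len - 1L)
      rows <- c(rows, list(read_row(next_well(), "F", rd, "single")))
    }
    dplyr::bind_rows(rows)
  })
}
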