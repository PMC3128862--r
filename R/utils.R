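#' Round half away from zero
#'
#' Plain decimal rounding where .5 always rounds up in magnitude (so 2.25
#' rounds to 2.3 at one decimal), matching how percentages and ratios are
#' conventionally reported in microbiology papers, rather than the IEEE
#' round-half-even used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded at `digits` decimals.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
  out
}

# reverse complement of plain character DNA; Biostrings does the work so
# IUPAC letters and N are handled consistently
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# derive a per-operation sub-seed from one global integer seed; fixed
# offsets keep each generator independently re-runnable while staying
# inside 32-bit integer range
sub_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

clone_id_regex <- "^(.+)_P([0-9]+)_([A-Z])([0-9]+)\\.([FR])$"

#' Compose a clone read identifier
#'
#' Clone ids follow the fixed grammar `<lib>_P<plate>_<rowletter><colnumber>.<F|R>`
#' (e.g. `MBv_P01_A05.F`), which the contig classifier parses to decide
#' whether contig members came from the same clone or from adjacent wells
#' of a library plate.
#'
#' @param library library name.
#' @param plate plate number (1-based).
#' @param well_row row letter ("A".."H" on a 96-well plate).
#' @param well_col column number (1-based).
#' @param direction "F" or "R" sequencing direction.
#' @return character vector of clone ids.
#' @export
format_clone_id <- function(library, plate, well_row, well_col, direction) {
  sprintf("%s_P%02d_%s%02d.%s", library, plate, well_row, well_col, direction)
}

#' Parse clone read identifiers
#'
#' Inverse of [format_clone_id()]. Ids that do not match the grammar are
#' returned with `ok = FALSE` and NA fields.
#'
#' @param ids character vector of clone ids.
#' @return a tibble with columns `id`, `library`, `plate`, `well_row`,
#'   `well_col`, `direction`, `ok`.
#' @export
parse_clone_id <- function(ids) {
  m <- regmatches(ids, regexec(clone_id_regex, ids))
  ok <- lengths(m) == 6L
  get <- function(k) vapply(m, function(g) if (length(g) == 6L) g[[k]] else NA_character_, "")
  tibble::tibble(
    id = ids,
    library = get(2L),
    plate = ifelse(ok, as.integer(get(3L)), NA_integer_),
    well_row = get(4L),
    well_col = ifelse(ok, as.integer(get(5L)), NA_integer_),
    direction = get(6L),
    ok = ok
  )
}

#' Read a FASTA file into a read table
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `sequence`, `length`.
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = names(x),
    sequence = unname(as.character(x)),
    length = Biostrings::width(x)
  )
}

#' Write a read table to FASTA
#'
#' @param reads a tibble with at least `id` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Serialises a summary object (e.g. a `virus_summary` or
#' `accounting_report`) to pretty-printed JSON.
#'
#' @param x a list-like report object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
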