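#' Buoyant density of a gradient fraction
#'
#' @param mass fraction mass in g.
#' @param volume fraction volume in ml.
#' @return density in g/ml.
#' @export
fraction_density <- function(mass, volume) {
  if (any(mass <= 0) || any(volume <= 0)) {
    stop("fraction_density: mass and volume must be positive", call. = FALSE)
  }
  mass / volume
}

#' Total particles recovered from selected gradient fractions
#'
#' @param fractions a gradient tibble (columns `vlp_per_ml`,
#'   `volume_ml`), already subset to the harvested fractions.
#' @return total particle count.
#' @export
total_particles <- function(fractions) {
  if (nrow(fractions) == 0) {
    stop("total_particles: empty fraction selection", call. = FALSE)
  }
  sum(fractions$vlp_per_ml * fractions$volume_ml)
}

#' Average DNA mass per particle, in attograms
#'
#' @param dna_mass DNA yield in g.
#' @param n_particles particle count.
#' @return attograms per particle, rounded half-up to the nearest
#'   integer.
#' @export
dna_per_particle <- function(dna_mass, n_particles) {
  if (dna_mass <= 0) stop("dna_per_particle: dna_mass must be positive", call. = FALSE)
  if (n_particles <= 0) stop("dna_per_particle: zero particles", call. = FALSE)
  round_half_up(dna_mass * 1e18 / n_particles)
}

avogadro <- 6.02214076e23

#' Genome size implied by a DNA mass
#'
#' Converts an average per-particle DNA mass into the double-stranded
#' genome length it implies, at `daltons_per_bp` grams per mole per
#' base pair. The default of 660 Da/bp is the standard dsDNA value;
#' 42 ag corresponds to about 38 kb.
#'
#' @param mass_ag DNA mass in attograms.
#' @param daltons_per_bp molar mass per base pair.
#' @return genome size in bp (report at the nearest kb via
#'   `round_half_up(bp / 1000)`).
#' @export
genome_size_from_mass <- function(mass_ag, daltons_per_bp = 660) {
  if (any(mass_ag <= 0)) stop("genome_size_from_mass: mass must be positive", call. = FALSE)
  mass_ag * 1e-18 * avogadro / daltons_per_bp
}

#' Recovery efficiency range
#'
#' Percentage of the particles originally present in the filtered
#' volume that survived concentration and purification, bracketed by a
#' historical abundance range for the site: the low estimate uses the
#' high abundance and vice versa.
#'
#' @param n_recovered particles recovered.
#' @param volume_filtered_l volume of water filtered, in liters.
#' @param abundance_range `c(low, high)` particles per liter.
#' @return `c(low, high)` percentages at one decimal.
#' @export
recovery_range <- function(n_recovered, volume_filtered_l, abundance_range) {
  stopifnot(n_recovered > 0, volume_filtered_l > 0, all(abundance_range > 0),
            abundance_range[1] <= abundance_range[2])
  c(
    low = round_half_up(100 * n_recovered / (volume_filtered_l * abundance_range[2]), 1),
    high = round_half_up(100 * n_recovered / (volume_filtered_l * abundance_range[1]), 1)
  )
}

#' Expected appearances of a single-copy gene in the library
#'
#' How many times a gene present once per genome could appear among the
#' sequenced bases if all library DNA were viral: total bases divided
#' by the average genome size.
#'
#' @param total_library_bases total bases sequenced.
#' @param genome_size_bp average genome size in bp.
#' @return expected copies, rounded half-up to one decimal.
#' @export
expected_gene_copies <- function(total_library_bases, genome_size_bp) {
  stopifnot(total_library_bases > 0, genome_size_bp > 0)
  round_half_up(total_library_bases / genome_size_bp, 1)
}

#' Full particle / DNA accounting report
#'
#' Chains the accounting operations: total particles from the selected
#' gradient fractions, DNA mass per particle, the implied average
#' genome size, recovery efficiency against a historical abundance
#' range, and the expected number of appearances of a single-copy viral
#' gene in the sequenced library.
#'
#' @param gradient gradient tibble (see [simulate_gradient()] /
#'   [read_gradient_tsv()]).
#' @param selected_fractions indices of harvested fractions.
#' @param dna_mass_g DNA yield in g.
#' @param volume_filtered_l seawater volume filtered, in liters.
#' @param abundance_range `c(low, high)` historical particles per liter.
#' @param total_library_bases total bases sequenced.
#' @param daltons_per_bp dsDNA molar mass per bp.
#' @return a list of class `accounting_report`.
#' @export
accounting_report <- function(gradient, selected_fractions, dna_mass_g,
                              volume_filtered_l, abundance_range,
                              total_library_bases, daltons_per_bp = 660) {
  sel <- gradient[gradient$fraction %in% selected_fractions, , drop = FALSE]
  total <- total_particles(sel)
  ag <- dna_per_particle(dna_mass_g, total)
  bp <- genome_size_from_mass(ag, daltons_per_bp)
  structure(list(
    total_particles = total,
    dna_mass = dna_mass_g,
    ag_per_particle = ag,
    genome_size_bp = bp,
    recovery_pct_range = recovery_range(total, volume_filtered_l, abundance_range),
    expected_gene_copies = expected_gene_copies(total_library_bases, bp)
  ), class = "accounting_report")
}

#' @export
print.accounting_report <- function(x, ...) {
  r <- x$recovery_pct_range
  cat(sprintf("particles recovered : %.3g\n", x$total_particles))
  cat(sprintf("DNA per particle    : %d ag\n", as.integer(x$ag_per_particle)))
  cat(sprintf("implied genome size : %d kb\n",
              as.integer(round_half_up(x$genome_size_bp / 1000))))
  cat(sprintf("recovery (estimate) : %d-%d %% (%.1f-%.1f %%)\n",
              as.integer(round_half_up(r[1])), as.integer(round_half_up(r[2])),
              r[1], r[2]))
  cat(sprintf("expected single-copy gene appearances: %.1f\n",
              x$expected_gene_copies))
  invisible(x)
}
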