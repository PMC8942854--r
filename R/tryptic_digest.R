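# In-silico tryptic digestion under standard search-engine constraints
# (strictly tryptic, bounded missed cleavages, length and monoisotopic
# mass windows), plus enumeration of peptides spanning substituted sites.

# Monoisotopic residue masses (Da), standard values; water added once per
# peptide. Modifications (TMT 229.162932, iTRAQ 144.1021, carbamidomethyl
# 57.021464) are upstream search-engine concerns and are not applied.
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO_MASS <- 18.010565

#' Monoisotopic mass of an unmodified peptide
#'
#' Sum of standard monoisotopic residue masses plus one water
#' (18.010565 Da).
#'
#' @param peptide Residue string (or character vector of them).
#' @return Numeric vector of masses in Daltons.
#' @export
#' @examples
#' monoisotopic_mass("G")        # 75.03203
#' monoisotopic_mass("AAAAAAR")  # 600.33434
monoisotopic_mass <- function(peptide) {
  vapply(peptide, function(p) {
    assert_peptide(p)
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(RESIDUE_MONO_MASS[chars]) + WATER_MONO_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Digestion configuration
#'
#' Defaults mirror common "strictly tryptic" engine settings: at most 2
#' missed cleavages, peptide length 7-50 residues, monoisotopic mass
#' 500-5000 Da. The proline rule (no cleavage after K/R when the next
#' residue is P) is on by default and exposed as a flag.
#'
#' @param max_missed_cleavages Maximum internal uncut K/R sites.
#' @param min_length,max_length Peptide length window (residues).
#' @param min_mass,max_mass Monoisotopic mass window (Da).
#' @param proline_rule Suppress cleavage before proline?
#' @return A list of class `digest_config`.
#' @export
digest_config <- function(max_missed_cleavages = 2L, min_length = 7L,
                          max_length = 50L, min_mass = 500,
                          max_mass = 5000, proline_rule = TRUE) {
  stopifnot(max_missed_cleavages >= 0L, min_length >= 1L,
            min_length <= max_length, min_mass >= 0, min_mass <= max_mass)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 min_mass = min_mass, max_mass = max_mass,
                 proline_rule = isTRUE(proline_rule)),
            class = "digest_config")
}

#' Tryptic digest of a protein sequence
#'
#' Cleaves C-terminal to K or R (not before P under the proline rule);
#' reported peptides are all runs of at most `max_missed_cleavages + 1`
#' consecutive fragments passing the length and mass filters, sorted by
#' (start, end). The protein N-terminal methionine is not cleaved and no
#' semi-tryptic forms are produced.
#'
#' @param sequence Protein residue string.
#' @param config A [digest_config()].
#' @param accession Optional source accession carried into the output.
#' @return Tibble with columns `source_accession`, `sequence`, `start`,
#'   `end`, `missed_cleavages`, `mono_mass`.
#' @export
#' @examples
#' digest("MKAAAAAAR")$sequence  # "MKAAAAAAR", "AAAAAAR"
digest <- function(sequence, config = digest_config(),
                   accession = NA_character_) {
  assert_peptide(sequence, "sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)

  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (config$proline_rule && length(cut_after) > 0L) {
    cut_after <- cut_after[chars[cut_after + 1L] != "P"]
  }
  bounds <- c(0L, cut_after, n)         # fragment boundaries
  m <- length(bounds) - 1L              # number of fragments

  res_mass <- unname(RESIDUE_MONO_MASS[chars])
  cmass <- c(0, cumsum(res_mass))

  # every run of <= mc+1 consecutive fragments, enumerated vectorized:
  # first-fragment index a, last-fragment index b = a..min(m, a+mc)
  n_runs <- pmin(m, seq_len(m) + config$max_missed_cleavages) - seq_len(m) + 1L
  a_idx <- rep.int(seq_len(m), n_runs)
  mc_cnt <- sequence(n_runs) - 1L
  b_idx <- a_idx + mc_cnt
  starts <- bounds[a_idx] + 1L
  ends <- bounds[b_idx + 1L]
  len <- ends - starts + 1L
  mass <- cmass[ends + 1L] - cmass[starts] + WATER_MONO_MASS
  keep <- len >= config$min_length & len <= config$max_length &
    mass >= config$min_mass & mass <= config$max_mass
  starts <- starts[keep]; ends <- ends[keep]
  mc_cnt <- mc_cnt[keep]; mass <- mass[keep]
  if (length(starts) == 0L) {
    return(tibble::tibble(source_accession = character(),
                          sequence = character(), start = integer(),
                          end = integer(), missed_cleavages = integer(),
                          mono_mass = numeric()))
  }
  ord <- order(starts, ends)
  tibble::tibble(
    source_accession = accession,
    sequence = substring(sequence, starts[ord], ends[ord]),
    start = starts[ord], end = ends[ord],
    missed_cleavages = mc_cnt[ord], mono_mass = mass[ord]
  )
}

# internal alias used by database-construction code
digest_sequence <- function(sequence, config = digest_config()) {
  digest(sequence, config)
}

#' Tryptic peptides of a substituted entry spanning its tryptophan sites
#'
#' Digests the substituted sequence and keeps only the peptides whose
#' span covers at least one original tryptophan position — the filter
#' applied after a search, where only peptides spanning the endogenous
#' tryptophan codon are informative about codon reassignment.
#'
#' @param entry One-row slice of the output of
#'   [substitute_tryptophans()] (or a list with `sequence`,
#'   `w_positions`, `target`, `source_accession` fields).
#' @param config A [digest_config()].
#' @return Tibble of spanning peptides with list-column `covered_sites`
#'   (the 1-based substituted positions inside the peptide) and column
#'   `target`.
#' @export
site_spanning_peptides <- function(entry, config = digest_config()) {
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1L)
    entry <- as.list(entry)
    entry$w_positions <- entry$w_positions[[1]]
  }
  peps <- digest(entry$sequence, config,
                 accession = entry$source_accession %||% NA_character_)
  if (nrow(peps) == 0L) {
    peps$covered_sites <- list()
    peps$target <- character(0)
    return(peps)
  }
  sites <- as.integer(entry$w_positions)
  covered <- purrr::map2(peps$start, peps$end,
                         function(s, e) sites[sites >= s & sites <= e])
  keep <- lengths(covered) > 0L
  peps <- peps[keep, ]
  peps$covered_sites <- covered[keep]
  peps$target <- if (nrow(peps)) entry$target else character(0)
  peps
}
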