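# Independent oracles and fixture builders used across the suite.

# residue monoisotopic masses, stated independently of the package's
# internal table so the digest oracle does not share its mass source
ORACLE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
  C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
  H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
  M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
ORACLE_WATER <- 18.010565

# Brute-force tryptic digest: enumerate EVERY substring of the protein
# and keep those whose boundaries are cleavage-consistent, whose count
# of internal cleavage sites is within the missed-cleavage budget, and
# which pass the length and mass filters. Returns start/end/mc tuples.
brute_digest <- function(sequence, config = digest_config()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_site <- chars %in% c("K", "R")
  if (config$proline_rule) {
    nxt_p <- c(chars[-1] == "P", FALSE)
    is_site <- is_site & !nxt_p
  }
  is_site[n] <- FALSE                      # C-terminus is a boundary anyway
  site_cum <- cumsum(is_site)

  grid <- expand.grid(s = seq_len(n), e = seq_len(n))
  grid <- grid[grid$e >= grid$s, ]
  start_ok <- grid$s == 1L | is_site[pmax(grid$s - 1L, 1L)]
  end_ok <- grid$e == n | is_site[grid$e]
  grid <- grid[start_ok & end_ok, ]
  sc0 <- c(0L, site_cum)           # sc0[i] = cleavage sites in 1..i-1
  internal <- sc0[grid$e] - sc0[grid$s]
  ok_mc <- internal <= config$max_missed_cleavages
  grid <- grid[ok_mc, ]
  internal <- internal[ok_mc]

  mass_cum <- c(0, cumsum(ORACLE_MASS[chars]))
  len <- grid$e - grid$s + 1L
  mass <- mass_cum[grid$e + 1L] - mass_cum[grid$s] + ORACLE_WATER
  keep <- len >= config$min_length & len <= config$max_length &
    mass >= config$min_mass & mass <= config$max_mass
  out <- data.frame(start = grid$s[keep], end = grid$e[keep],
                    missed_cleavages = internal[keep])
  out[order(out$start, out$end), ]
}

# Naive weighted-KS running sum, written as an explicit per-gene loop.
brute_gsea_es <- function(ranking, gene_set, p) {
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  metric <- unname(ranking[ord])
  hits <- genes %in% gene_set
  nr <- sum(abs(metric[hits])^p)
  running <- 0
  best <- 0
  for (i in seq_along(genes)) {
    if (hits[i]) {
      running <- running + if (nr > 0) abs(metric[i])^p / nr else 1 / sum(hits)
    } else {
      running <- running - 1 / (length(genes) - sum(hits))
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

random_protein <- function(n) {
  probs <- c(rep(0.9 / 17, 17), K = 0.04, R = 0.04, W = 0.02)
  names(probs)[1:17] <- setdiff(aa_alphabet(), c("K", "R", "W"))
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# two-protein toy proteome used by the mapping/calling fixtures
toy_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2"),
    gene = c("G1", "G2"),
    sequence = c("MKAAAWAARDDDDDDK", "MKYYYYYYRAAAFAARK")
  )
}

# evidence rows in the canonical shape, defaulting to detected
toy_evidence <- function(peptide, sample, replicate, condition, intensity) {
  tibble::tibble(peptide = peptide, protein = "", sample_id = sample,
                 replicate_id = replicate, condition = condition,
                 log_intensity = intensity,
                 detected = !is.na(intensity))
}

# minimal calls tibble carrying given per-target counts (for enrichment
# arithmetic tests)
fake_calls <- function(target_counts) {
  proto <- tibble::tibble(
    accession = character(), gene = character(), sites = list(),
    from_residue = character(), to_residue = character(),
    peptide = character(), samples_positive = list(),
    n_samples_positive = integer(), replicates_detected = list(),
    conditions_detected = character(), isobaric_pair = logical())
  rows <- purrr::imap(target_counts, function(k, t) {
    if (k == 0) return(proto)
    tibble::tibble(
      accession = sprintf("P%s%03d", t, seq_len(k)), gene = "",
      sites = replicate(k, 1L, simplify = FALSE),
      from_residue = "W", to_residue = t,
      peptide = sprintf("PEP%s%03d", t, seq_len(k)),
      samples_positive = replicate(k, "s1", simplify = FALSE),
      n_samples_positive = 1L,
      replicates_detected = replicate(k, c(tumour = 2L), simplify = FALSE),
      conditions_detected = "tumour", isobaric_pair = t %in% c("I", "L"))
  })
  dplyr::bind_rows(rows)
}

# shared small simulation scenario for fast repeated cohorts;
# dot-arguments override the scaled-down defaults
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_proteins = 12L, protein_length = c(150L, 250L),
               w_frequency = 0.015, n_tumour = 20L, n_normal = 20L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# noiseless variant: every planted event is observed and positive
noiseless_config <- function(seed = 1L, ...) {
  small_sim_config(seed = seed, intensity_sd = 1e-6, dropout = 0, ...)
}
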