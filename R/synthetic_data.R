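# Synthetic proteome / cohort generator with known ground truth. The
# generator emulates the statistical structure the cohort analysis
# assumes: tumour/normal samples with an IDO1 covariate, a W>F process
# whose per-locus rate increases with IDO1 in tumours, a uniform W>X
# background, log-normal reference-normalized intensities with Bernoulli
# dropout, and a replicate structure that makes the reproducibility
# filter exercisable. Events are planted at the peptide level
# (post-digest): the pipeline's input contract is peptide evidence, so
# simulating spectra would test nothing this package owns.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: a 40-protein proteome (200-400 residues, tryptophan at
#' its natural ~1.2% abundance, K/R at ~10% combined so tryptic peptides
#' are realistic), 50 tumour and 50 normal samples with 2 replicates
#' each, an IDO1-dependent W>F process in tumours
#' (`P(event) = plogis(base_rate + ido1_effect * IDO1)` per locus, IDO1
#' ~ N(1,1) in tumours and N(-1,1) in normals), and a uniform background
#' in which each non-F target fires independently at `background_rate`
#' per locus per sample.
#'
#' @param n_proteins Number of simulated proteins.
#' @param protein_length Length range `c(min, max)` in residues.
#' @param w_frequency Per-residue probability of tryptophan.
#' @param n_tumour,n_normal Sample counts per tissue class.
#' @param n_replicates Replicates per sample (>= 2 so the
#'   reproducibility filter can act).
#' @param ido1_effect Log-odds of a W>F event per unit IDO1 (applied in
#'   tumours only).
#' @param base_rate Logit of the per-locus W>F event probability at
#'   IDO1 = 0 (and everywhere in normals).
#' @param background_rate Per-locus, per-sample probability of each
#'   non-F W>X event.
#' @param intensity_mean,intensity_sd Log2 intensity distribution of
#'   detected substitutant peptides (reference-normalized; the mean must
#'   sit above 0 for events to pass the positivity rule).
#' @param dropout Probability that a true peptide observation is lost in
#'   a given replicate.
#' @param n_immune_genes Size of the immune expression module whose
#'   expression tracks per-sample W>F burden (for GSEA power tests).
#' @param immune_cor Correlation strength of that module.
#' @param seed Integer seed; the proteome and the cohort use split
#'   streams derived from it, so changing sample counts does not perturb
#'   the proteome.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 40L, protein_length = c(200L, 400L),
                       w_frequency = 0.012, n_tumour = 50L,
                       n_normal = 50L, n_replicates = 2L,
                       ido1_effect = 1.5, base_rate = -3,
                       background_rate = 0.002, intensity_mean = 1,
                       intensity_sd = 0.5, dropout = 0.05,
                       n_immune_genes = 30L, immune_cor = 0.8,
                       seed = 1L) {
  stopifnot(w_frequency >= 0, w_frequency <= 1,
            background_rate >= 0, background_rate <= 1,
            dropout >= 0, dropout <= 1,
            n_replicates >= 2L, intensity_sd > 0,
            length(protein_length) == 2L,
            protein_length[1] <= protein_length[2])
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 w_frequency = w_frequency,
                 n_tumour = as.integer(n_tumour),
                 n_normal = as.integer(n_normal),
                 n_replicates = as.integer(n_replicates),
                 ido1_effect = ido1_effect, base_rate = base_rate,
                 background_rate = background_rate,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, dropout = dropout,
                 n_immune_genes = as.integer(n_immune_genes),
                 immune_cor = immune_cor, seed = as.integer(seed)),
            class = "sim_config")
}

# residue sampling distribution: W at its configured frequency, K and R
# boosted to ~5% each, remainder spread over the other 17 residues
residue_probs <- function(w_frequency) {
  aa <- aa_alphabet()
  p <- setNames(numeric(length(aa)), aa)
  p["W"] <- w_frequency
  p["K"] <- p["R"] <- 0.05
  rest <- setdiff(aa, c("W", "K", "R"))
  p[rest] <- (1 - w_frequency - 0.10) / length(rest)
  p
}

#' Simulate a proteome with controlled tryptophan content
#'
#' Residues are drawn i.i.d. from [residue_probs()]; deterministic given
#' the config seed. Accessions are `SIMP%05d` and gene symbols
#' `SIMG%05d`.
#'
#' @param config A [sim_config()].
#' @return Protein record tibble (as from [read_fasta()]).
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  probs <- residue_probs(config$w_frequency)
  len_range <- seq.int(config$protein_length[1], config$protein_length[2])
  lens <- len_range[sample.int(length(len_range), config$n_proteins,
                               replace = TRUE)]
  sequences <- vapply(lens, function(n)
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  tibble::tibble(
    accession = sprintf("SIMP%05d", seq_len(config$n_proteins)),
    gene = sprintf("SIMG%05d", seq_len(config$n_proteins)),
    sequence = sequences
  )
}

#' Precompute the plantable substitutant loci of a simulated proteome
#'
#' Builds the full substituted database and peptide index once, then
#' derives the loci at which the cohort generator can plant events: for
#' every tryptophan site and target residue, the shortest uniquely
#' mapping digest peptide spanning the site (a peptide whose tryptic
#' fragment contains two tryptophans yields a single multi-site locus).
#' Reusable across seeds, so repeated cohort simulations do not re-digest
#' the database.
#'
#' @param proteome Output of [simulate_proteome()].
#' @param digest_cfg A [digest_config()].
#' @return List with `entries`, `index` and the `loci` tibble
#'   (`accession`, `gene`, `target`, `sites`, `peptide`,
#'   `canonical_peptide`).
#' @export
prepare_simulation <- function(proteome, digest_cfg = digest_config()) {
  entries <- substitute_tryptophans(proteome)
  index <- peptide_index(proteome, entries, digest_cfg)
  cand <- index[index$class == "substitutant", ]
  if (nrow(cand) == 0L) {
    stop("no digest-valid uniquely mapping tryptophan-spanning peptides; ",
         "use longer proteins or a higher tryptophan frequency",
         call. = FALSE)
  }
  per_site <- tidyr::unnest(
    cand[, c("peptide", "accession", "gene", "target", "sites",
             "start", "end")],
    "sites")
  per_site$pep_len <- nchar(per_site$peptide)
  # shortest spanning peptide per (protein, target, site); ties broken
  # by start position
  ord <- order(per_site$accession, per_site$target, per_site$sites,
               per_site$pep_len, per_site$start)
  per_site <- per_site[ord, ]
  key <- paste(per_site$accession, per_site$target, per_site$sites)
  per_site <- per_site[!duplicated(key), ]

  loci <- dplyr::distinct(per_site, .data$accession, .data$target,
                          .data$peptide, .keep_all = TRUE)
  full_sites <- index$sites[match(loci$peptide, index$peptide)]
  src_seq <- proteome$sequence[match(loci$accession, proteome$accession)]
  loci <- tibble::tibble(
    accession = loci$accession, gene = loci$gene, target = loci$target,
    sites = full_sites, peptide = loci$peptide,
    canonical_peptide = substring(src_seq, loci$start, loci$end)
  )
  list(entries = entries, index = index, loci = loci)
}

#' Simulate a tumour/normal proteomics cohort with planted substitutants
#'
#' Generates the peptide evidence table, sample annotation, expression
#' matrix and ground truth for one cohort under the configured W>F
#' process (see [sim_config()]). All randomness derives from
#' `config$seed` through a stream separate from the proteome's, so the
#' same proteome supports many cohort draws.
#'
#' @param proteome Output of [simulate_proteome()].
#' @param config A [sim_config()].
#' @param prep Optional precomputed [prepare_simulation()] result.
#' @param emit_canonical Also emit the canonical counterpart peptides of
#'   every W>F locus (default `TRUE`).
#' @return List with `evidence`, `annotation`, `expression` (matrix) and
#'   `truth` (list: `planted_calls`, `f_counts` per sample, `params`).
#' @export
simulate_cohort <- function(proteome, config = sim_config(), prep = NULL,
                            emit_canonical = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(prep)) prep <- prepare_simulation(proteome)
  set.seed((config$seed + 1000003L) %% 2147483647L)

  n_s <- config$n_tumour + config$n_normal
  annotation <- tibble::tibble(
    sample_id = c(sprintf("T%03d", seq_len(config$n_tumour)),
                  sprintf("N%03d", seq_len(config$n_normal))),
    tissue = rep(c("tumour", "normal"),
                 c(config$n_tumour, config$n_normal)),
    ido1_log_intensity = c(rnorm(config$n_tumour, 1, 1),
                           rnorm(config$n_normal, -1, 1)),
    cohort = "SIM"
  )

  loci_f <- prep$loci[prep$loci$target == "F", ]
  loci_bg <- prep$loci[prep$loci$target != "F", ]
  is_tum <- annotation$tissue == "tumour"
  p_f <- plogis(config$base_rate +
                  config$ido1_effect * annotation$ido1_log_intensity *
                  as.numeric(is_tum))

  ev_f <- matrix(runif(nrow(loci_f) * n_s), nrow(loci_f), n_s) <
    matrix(p_f, nrow(loci_f), n_s, byrow = TRUE)
  ev_bg <- matrix(runif(nrow(loci_bg) * n_s), nrow(loci_bg), n_s) <
    config$background_rate

  event_rows <- function(mask, loci) {
    hit <- which(mask, arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      return(tibble::tibble(peptide = character(), protein = character(),
                            sample_id = character(), locus = integer()))
    }
    tibble::tibble(peptide = loci$peptide[hit[, 1]],
                   protein = loci$accession[hit[, 1]],
                   sample_id = annotation$sample_id[hit[, 2]],
                   locus = as.integer(hit[, 1]))
  }
  events <- dplyr::bind_rows(f = event_rows(ev_f, loci_f),
                             bg = event_rows(ev_bg, loci_bg),
                             .id = "source")

  expand_replicates <- function(rows, mean_int) {
    if (nrow(rows) == 0L) {
      out <- rows[0, ]
      out$replicate_id <- character(0)
      out$log_intensity <- numeric(0)
      return(out)
    }
    reps <- tidyr::expand_grid(
      i = seq_len(nrow(rows)),
      replicate_id = sprintf("r%d", seq_len(config$n_replicates)))
    out <- rows[reps$i, ]
    out$replicate_id <- reps$replicate_id
    out$log_intensity <- rnorm(nrow(out), mean_int, config$intensity_sd)
    out[runif(nrow(out)) >= config$dropout, ]
  }
  sub_rows <- expand_replicates(events, config$intensity_mean)

  canon_rows <- NULL
  if (emit_canonical && nrow(loci_f) > 0L) {
    canon <- dplyr::distinct(
      tibble::tibble(peptide = loci_f$canonical_peptide,
                     protein = loci_f$accession), .data$peptide,
      .keep_all = TRUE)
    grid <- tidyr::expand_grid(i = seq_len(nrow(canon)),
                               sample_id = annotation$sample_id)
    canon_all <- canon[grid$i, ]
    canon_all$sample_id <- grid$sample_id
    canon_rows <- expand_replicates(canon_all, 0)
  }

  evidence <- dplyr::bind_rows(sub_rows, canon_rows)
  tissue_of <- setNames(annotation$tissue, annotation$sample_id)
  if (nrow(evidence) > 0L) {
    evidence$condition <- unname(tissue_of[evidence$sample_id])
    evidence$detected <- TRUE
  } else {
    evidence$condition <- character(0)
    evidence$detected <- logical(0)
  }
  evidence <- evidence[, intersect(
    c("peptide", "protein", "sample_id", "replicate_id", "condition",
      "log_intensity", "detected"), names(evidence))]

  # expression: protein genes are noise; an immune module tracks the
  # per-sample planted W>F burden
  f_counts <- setNames(as.integer(colSums(ev_f)), annotation$sample_id)
  gene_expr <- matrix(rnorm(nrow(proteome) * n_s), nrow(proteome), n_s,
                      dimnames = list(proteome$gene, annotation$sample_id))
  z <- if (stats::sd(f_counts) > 0) as.numeric(scale(f_counts)) else
    rep(0, n_s)
  imm_names <- sprintf("IMM%03d", seq_len(config$n_immune_genes))
  imm_expr <- matrix(rep(config$immune_cor * z,
                         each = config$n_immune_genes) +
                       rnorm(config$n_immune_genes * n_s, 0, 0.6),
                     config$n_immune_genes, n_s,
                     dimnames = list(imm_names, annotation$sample_id))
  expression <- rbind(gene_expr, imm_expr)

  planted <- dplyr::bind_rows(
    planted_from_events(events[events$source == "f", ], loci_f, "F"),
    planted_from_events(events[events$source == "bg", ], loci_bg, NULL))

  list(evidence = evidence, annotation = annotation,
       expression = expression,
       truth = list(planted_calls = planted, f_counts = f_counts,
                    params = config),
       prep = prep)
}

# collapse event rows to the planted-call unit: one row per locus with
# the set of samples in which the event fired
planted_from_events <- function(events, loci, target) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(accession = character(), gene = character(),
                          sites = list(), to_residue = character(),
                          peptide = character(), samples_event = list()))
  }
  by_locus <- split(events$sample_id, events$locus)
  ids <- as.integer(names(by_locus))
  tibble::tibble(
    accession = loci$accession[ids],
    gene = loci$gene[ids],
    sites = loci$sites[ids],
    to_residue = if (is.null(target)) loci$target[ids] else target,
    peptide = loci$peptide[ids],
    samples_event = purrr::map(by_locus, ~ sort(unique(.x)))
  )
}

#' Precision and recall of called substitutants against planted truth
#'
#' Calls and planted events are matched on (protein, site set, target
#' residue). When no calls were made for a target, precision is reported
#' as 1 with `undefined_precision = TRUE` and recall as 0.
#'
#' @param calls Output of [call_substitutants()].
#' @param truth The `truth` element of [simulate_cohort()] (or its
#'   `planted_calls` tibble).
#' @return Tibble with one row per planted or called target residue:
#'   `target`, `n_planted`, `n_called`, `n_matched`, `precision`,
#'   `recall`, `undefined_precision`.
#' @export
evaluate_recovery <- function(calls, truth) {
  planted <- if (is.data.frame(truth)) truth else truth$planted_calls
  if (is.null(planted) || nrow(planted) == 0L) {
    stop("ground truth is empty; nothing to evaluate", call. = FALSE)
  }
  key <- function(acc, sites, to)
    paste(acc, vapply(sites, paste, character(1), collapse = ";"), to)
  truth_keys <- key(planted$accession, planted$sites, planted$to_residue)
  call_keys <- if (nrow(calls) > 0L)
    key(calls$accession, calls$sites, calls$to_residue) else character(0)

  targets <- sort(union(planted$to_residue,
                        if (nrow(calls)) calls$to_residue else character(0)))
  purrr::map_dfr(targets, function(t) {
    tk <- unique(truth_keys[planted$to_residue == t])
    ck <- unique(call_keys[if (nrow(calls)) calls$to_residue == t else
      logical(0)])
    matched <- length(intersect(tk, ck))
    undef <- length(ck) == 0L
    tibble::tibble(
      target = t, n_planted = length(tk), n_called = length(ck),
      n_matched = matched,
      precision = if (undef) 1 else matched / length(ck),
      recall = if (length(tk) == 0L) NA_real_ else matched / length(tk),
      undefined_precision = undef
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Emits `proteome.fasta`, `evidence.tsv`, `annotation.tsv`,
#' `expression.tsv`, `planted_calls.tsv` and a copy of the packaged
#' synthetic T-cell activation GMT into `dir`.
#'
#' @param proteome,sim Outputs of [simulate_proteome()] and
#'   [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(proteome, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(proteome, file.path(dir, "proteome.fasta"))
  readr::write_tsv(sim$evidence, file.path(dir, "evidence.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"),
                   progress = FALSE)
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  flat <- sim$truth$planted_calls
  flat$sites <- vapply(flat$sites, paste, character(1), collapse = ";")
  flat$samples_event <- vapply(flat$samples_event, paste, character(1),
                               collapse = ";")
  readr::write_tsv(flat, file.path(dir, "planted_calls.tsv"),
                   progress = FALSE)
  gmt <- system.file("extdata", "tcell_activation_synthetic.gmt",
                     package = "substiscan")
  if (nzchar(gmt)) file.copy(gmt, file.path(dir, basename(gmt)),
                             overwrite = TRUE)
  invisible(dir)
}
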