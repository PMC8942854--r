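# Turning peptide evidence tables into validated substitutant calls:
# peptide-to-site mapping with a uniqueness-versus-canonical check,
# positivity and reproducibility filtering, and condition partitioning.
#
# The uniqueness check is explicit here (a search engine performs it
# implicitly through its competitive target database): this caller
# consumes peptide lists, not spectra, so a peptide that also occurs in
# any canonical protein cannot be claimed as a substitutant.

#' Call-filtering configuration
#'
#' @param positivity_threshold A sample is positive for a peptide when
#'   its reference-normalized log2 intensity is strictly above this
#'   value (default 0: "above 0 on the log scale").
#' @param min_replicates Minimum biological replicates of at least one
#'   condition in which a peptide must be detected (default 2).
#' @param require_unique_vs_canonical Reject peptides that are a
#'   substring of any canonical protein (default `TRUE`).
#' @param any_replicate If `TRUE`, a sample is positive when any of its
#'   replicates is positive; default requires all observed replicates of
#'   the sample to be positive (the conservative reading).
#' @param exact_replicates If `TRUE`, require detection in exactly
#'   `min_replicates` replicates rather than at least that many.
#' @param presence_counts If `TRUE`, rows with missing intensity count as
#'   detected-but-not-positive toward replicate detection; default only
#'   positive rows count.
#' @return A list of class `call_filter_config`.
#' @export
call_filter_config <- function(positivity_threshold = 0,
                               min_replicates = 2L,
                               require_unique_vs_canonical = TRUE,
                               any_replicate = FALSE,
                               exact_replicates = FALSE,
                               presence_counts = FALSE) {
  stopifnot(min_replicates >= 1L)
  structure(list(positivity_threshold = positivity_threshold,
                 min_replicates = as.integer(min_replicates),
                 require_unique_vs_canonical = isTRUE(require_unique_vs_canonical),
                 any_replicate = isTRUE(any_replicate),
                 exact_replicates = isTRUE(exact_replicates),
                 presence_counts = isTRUE(presence_counts)),
            class = "call_filter_config")
}

#' Index the peptides of a substituted database for site assignment
#'
#' Digests every substituted entry, keeps the peptides spanning at least
#' one original tryptophan position, and classifies each distinct peptide
#' sequence:
#' \describe{
#'   \item{substitutant}{maps to exactly one locus (one source protein,
#'     one target residue, one position span).}
#'   \item{canonical}{also occurs as a substring of a canonical protein,
#'     so it carries no substitution evidence.}
#'   \item{ambiguous}{identical sequence arises from several proteins,
#'     target residues, or positions.}
#' }
#'
#' @param proteome Canonical proteome tibble (see [read_fasta()]).
#' @param entries Output of [substitute_tryptophans()].
#' @param config A [digest_config()].
#' @return Tibble with columns `peptide`, `class`, `accession`, `gene`,
#'   `target`, `sites` (list), `start`, `end`.
#' @export
peptide_index <- function(proteome, entries, config = digest_config()) {
  if (nrow(entries) == 0L) {
    return(tibble::tibble(peptide = character(), class = character(),
                          accession = character(), gene = character(),
                          target = character(), sites = list(),
                          start = integer(), end = integer()))
  }
  per_entry <- purrr::map(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    peps <- site_spanning_peptides(e, config)
    if (nrow(peps) == 0L) return(NULL)
    tibble::tibble(peptide = peps$sequence,
                   accession = e$source_accession,
                   gene = if ("gene" %in% names(e)) e$gene else "",
                   target = e$target,
                   sites = peps$covered_sites,
                   start = peps$start, end = peps$end)
  })
  all_matches <- dplyr::bind_rows(per_entry)
  # a peptide may be reached at several missed-cleavage depths with the
  # same span; collapse to distinct loci
  all_matches <- dplyr::distinct(
    all_matches, .data$peptide, .data$accession, .data$target, .data$start,
    .keep_all = TRUE)

  canon_cat <- paste(proteome$sequence, collapse = "#")
  pep_levels <- unique(all_matches$peptide)
  is_canon <- stringr::str_detect(canon_cat, stringr::fixed(pep_levels))
  canon_set <- pep_levels[is_canon]

  grouped <- dplyr::group_by(all_matches, .data$peptide)
  n_loci <- dplyr::summarise(grouped, n = dplyr::n(),
                             n_acc = dplyr::n_distinct(.data$accession),
                             n_tgt = dplyr::n_distinct(.data$target))
  cls <- ifelse(n_loci$peptide %in% canon_set, "canonical",
                ifelse(n_loci$n > 1L, "ambiguous", "substitutant"))
  class_map <- setNames(cls, n_loci$peptide)

  idx <- all_matches
  idx$class <- unname(class_map[idx$peptide])
  # one row per peptide; locus columns meaningful only for unambiguous
  idx <- idx[!duplicated(idx$peptide), ]
  blank <- idx$class == "ambiguous"
  idx$accession[blank] <- NA_character_
  idx$gene[blank] <- NA_character_
  idx$target[blank] <- NA_character_
  idx$sites[blank] <- list(integer(0))
  idx$start[blank] <- NA_integer_
  idx$end[blank] <- NA_integer_
  idx[, c("peptide", "class", "accession", "gene", "target", "sites",
          "start", "end")]
}

#' Classify one peptide against the canonical proteome and substituted
#' database
#'
#' Convenience single-peptide interface over the same rules as
#' [peptide_index()]: `canonical` when the peptide is a substring of any
#' canonical protein, `substitutant` when it maps to exactly one
#' substituted locus, `ambiguous` when identical sequences arise from
#' multiple proteins/targets/positions, and `unmapped` otherwise.
#'
#' @param peptide Residue string.
#' @param proteome Canonical proteome tibble.
#' @param entries Output of [substitute_tryptophans()].
#' @return List with elements `class` and `matches` (tibble of
#'   `accession`, `target`, `sites`, `start`, `end`).
#' @export
map_peptide_to_sites <- function(peptide, proteome, entries) {
  assert_peptide(peptide)
  if (any(stringr::str_detect(proteome$sequence, stringr::fixed(peptide)))) {
    return(list(class = "canonical", matches = NULL))
  }
  hits <- which(stringr::str_detect(entries$sequence,
                                    stringr::fixed(peptide)))
  rows <- purrr::map(hits, function(i) {
    locs <- stringr::str_locate_all(entries$sequence[i],
                                    stringr::fixed(peptide))[[1]]
    sites_all <- entries$w_positions[[i]]
    purrr::map(seq_len(nrow(locs)), function(j) {
      s <- locs[j, 1]; e <- locs[j, 2]
      covered <- sites_all[sites_all >= s & sites_all <= e]
      if (length(covered) == 0L) return(NULL)
      tibble::tibble(accession = entries$source_accession[i],
                     target = entries$target[i],
                     sites = list(as.integer(covered)),
                     start = as.integer(s), end = as.integer(e))
    })
  })
  matches <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(matches) == 0L) return(list(class = "unmapped", matches = NULL))
  cls <- if (nrow(matches) > 1L) "ambiguous" else "substitutant"
  list(class = cls, matches = matches)
}

#' Call substitutants from a peptide evidence table
#'
#' Applies, in order: site assignment through the peptide index (only
#' peptides mapping to exactly one substituted locus survive; peptides
#' identical to a canonical substring are rejected when
#' `require_unique_vs_canonical`), the positivity rule (a sample is
#' positive when its reference-normalized log2 intensity is strictly
#' above the threshold), and the reproducibility rule (detection in at
#' least `min_replicates` biological replicates of at least one
#' condition). One call is emitted per (protein, sites, target residue,
#' peptide); a peptide covering several substituted tryptophans emits a
#' single multi-site call. W>I and W>L calls are flagged
#' `isobaric_pair = TRUE` since MS cannot distinguish leucine from
#' isoleucine.
#'
#' @param evidence Evidence tibble (see [read_evidence_table()]).
#' @param proteome,entries Canonical proteome and substituted entries,
#'   used to build the index when `index` is not supplied.
#' @param config A [call_filter_config()].
#' @param index Optional precomputed [peptide_index()] (recommended when
#'   calling repeatedly against the same database).
#' @param annotation Optional annotation tibble; when supplied, evidence
#'   referencing unknown samples is an error.
#' @param digest_cfg A [digest_config()] for index construction.
#' @return Tibble of calls with columns `accession`, `gene`, `sites`
#'   (list), `from_residue`, `to_residue`, `peptide`, `samples_positive`
#'   (list), `n_samples_positive`, `replicates_detected` (list of named
#'   integer vectors per condition), `conditions_detected`,
#'   `isobaric_pair`. The set of conditions observed in the evidence is
#'   attached as attribute `"conditions"`.
#' @export
call_substitutants <- function(evidence, proteome = NULL, entries = NULL,
                               config = call_filter_config(),
                               index = NULL, annotation = NULL,
                               digest_cfg = digest_config()) {
  stopifnot(inherits(config, "call_filter_config"))
  if (is.null(index)) {
    if (is.null(proteome) || is.null(entries)) {
      stop("supply either a precomputed index or proteome + entries",
           call. = FALSE)
    }
    index <- peptide_index(proteome, entries, digest_cfg)
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(unique(evidence$sample_id), annotation$sample_id)
    if (length(unknown) > 0L) {
      stop("evidence references sample(s) absent from annotation: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  keep_classes <- if (config$require_unique_vs_canonical) "substitutant"
                  else c("substitutant", "canonical")
  idx <- index[index$class %in% keep_classes & !is.na(index$accession), ]

  empty_calls <- tibble::tibble(
    accession = character(), gene = character(), sites = list(),
    from_residue = character(), to_residue = character(),
    peptide = character(), samples_positive = list(),
    n_samples_positive = integer(), replicates_detected = list(),
    conditions_detected = character(), isobaric_pair = logical())
  attr(empty_calls, "conditions") <- unique(evidence$condition)

  ev <- dplyr::inner_join(evidence, idx, by = "peptide",
                          relationship = "many-to-one")
  if (nrow(ev) == 0L) return(empty_calls)

  if (!"detected" %in% names(ev)) ev$detected <- !is.na(ev$log_intensity)
  ev$positive <- ev$detected & ev$log_intensity > config$positivity_threshold

  # replicate detection per locus x condition
  det <- if (config$presence_counts) ev else ev[ev$positive, ]
  rep_counts <- dplyr::summarise(
    dplyr::group_by(det, .data$peptide, .data$condition),
    n_rep = dplyr::n_distinct(paste(.data$sample_id, .data$replicate_id)),
    .groups = "drop")

  qualifies <- if (config$exact_replicates) {
    function(n) n == config$min_replicates
  } else {
    function(n) n >= config$min_replicates
  }
  rep_by_pep <- split(rep_counts, rep_counts$peptide)
  keep_pep <- names(rep_by_pep)[vapply(rep_by_pep, function(d)
    any(qualifies(d$n_rep)), logical(1))]
  if (length(keep_pep) == 0L) return(empty_calls)

  # sample positivity: default all observed replicates positive
  samp <- dplyr::summarise(
    dplyr::group_by(ev[ev$peptide %in% keep_pep, ],
                    .data$peptide, .data$sample_id),
    n_obs = sum(.data$detected), n_pos = sum(.data$positive),
    .groups = "drop")
  samp$sample_positive <- if (config$any_replicate) samp$n_pos >= 1L else
    samp$n_pos >= 1L & samp$n_pos == samp$n_obs

  pos_samples <- split(samp$sample_id[samp$sample_positive],
                       samp$peptide[samp$sample_positive])

  meta <- idx[match(keep_pep, idx$peptide), ]
  calls <- tibble::tibble(
    accession = meta$accession,
    gene = meta$gene,
    sites = meta$sites,
    from_residue = "W",
    to_residue = meta$target,
    peptide = keep_pep,
    samples_positive = purrr::map(keep_pep, function(p)
      sort(unique(pos_samples[[p]] %||% character(0)))),
    replicates_detected = purrr::map(keep_pep, function(p) {
      d <- rep_by_pep[[p]]
      if (is.null(d)) integer(0) else setNames(as.integer(d$n_rep), d$condition)
    }),
    isobaric_pair = meta$target %in% c("I", "L")
  )
  calls$n_samples_positive <- lengths(calls$samples_positive)
  calls$conditions_detected <- vapply(calls$replicates_detected, function(r)
    paste(sort(names(r)[qualifies(r)]), collapse = ";"), character(1))
  calls <- calls[order(calls$accession,
                       vapply(calls$sites, min, integer(1)),
                       calls$to_residue, calls$peptide), ]
  calls <- calls[, c("accession", "gene", "sites", "from_residue",
                     "to_residue", "peptide", "samples_positive",
                     "n_samples_positive", "replicates_detected",
                     "conditions_detected", "isobaric_pair")]
  attr(calls, "conditions") <- unique(evidence$condition)
  calls
}

#' Partition calls by the conditions in which they qualify
#'
#' A call qualifies in a condition when its replicate-detection count
#' there meets the reproducibility criterion; calls are counted as
#' specific to condition A, specific to B, or shared.
#'
#' @param calls Output of [call_substitutants()].
#' @param cond_a,cond_b Condition labels.
#' @param min_replicates Reproducibility criterion (default 2).
#' @return Named integer vector `c(only_a, only_b, both)`.
#' @export
condition_partition <- function(calls, cond_a, cond_b,
                                min_replicates = 2L) {
  known <- attr(calls, "conditions")
  if (!is.null(known) && length(known) > 0L) {
    unknown <- setdiff(c(cond_a, cond_b), known)
    if (length(unknown) > 0L) {
      stop("unknown condition label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(calls) == 0L) {
    return(c(only_a = 0L, only_b = 0L, both = 0L))
  }
  in_a <- vapply(calls$replicates_detected, function(r)
    isTRUE(r[cond_a] >= min_replicates), logical(1))
  in_b <- vapply(calls$replicates_detected, function(r)
    isTRUE(r[cond_b] >= min_replicates), logical(1))
  c(only_a = sum(in_a & !in_b), only_b = sum(!in_a & in_b),
    both = sum(in_a & in_b))
}
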