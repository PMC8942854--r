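# Construction of tryptophan-substituted search databases and the five
# reporter-construct databases covering aberrant decoding products
# (frameshift, codon reassignment, translational bypass).

#' Substitute every tryptophan in a proteome with each target residue
#'
#' For each W-containing protein and each target residue one variant
#' entry is produced in which *all* tryptophans are replaced
#' simultaneously by that residue (so peptides carrying two or three
#' W>target conversions exist in the database). Proteins without W emit
#' nothing. The default target set is the 17 residues other than W, K and
#' R: K and R are excluded to avoid creating new tryptic cleavage sites.
#'
#' @param proteome Tibble of protein records (see [read_fasta()]).
#' @param targets Character vector of substitution target residues.
#' @return Tibble with columns `source_accession`, `gene`, `target`,
#'   `sequence` and list-column `w_positions` (1-based positions of the
#'   original tryptophans).
#' @export
#' @examples
#' prot <- tibble::tibble(accession = "P1", gene = "", sequence = "MAWK")
#' substitute_tryptophans(prot, targets = "F")
substitute_tryptophans <- function(proteome, targets = default_targets()) {
  if (length(targets) == 0L) stop("targets must be non-empty", call. = FALSE)
  targets <- unique(toupper(targets))
  if ("W" %in% targets) stop("'W' is not a valid substitution target",
                             call. = FALSE)
  if (!all(targets %in% aa_alphabet())) {
    stop("invalid target residue(s): ",
         paste(setdiff(targets, aa_alphabet()), collapse = ", "),
         call. = FALSE)
  }
  has_w <- grepl("W", proteome$sequence, fixed = TRUE)
  src <- proteome[has_w, ]
  if (nrow(src) == 0L) {
    return(tibble::tibble(source_accession = character(), gene = character(),
                          target = character(), sequence = character(),
                          w_positions = list()))
  }
  w_pos <- gregexpr("W", src$sequence, fixed = TRUE)
  w_pos <- purrr::map(w_pos, as.integer)
  gene <- if ("gene" %in% names(src)) src$gene else rep("", nrow(src))

  out <- purrr::map(targets, function(t) {
    tibble::tibble(
      source_accession = src$accession,
      gene = gene,
      target = t,
      sequence = gsub("W", t, src$sequence, fixed = TRUE),
      w_positions = w_pos
    )
  })
  dplyr::bind_rows(out)
}

#' Write substituted entries as a FASTA search database
#'
#' Header convention: `>sub|<accession>|W2<target> POS=<p1;p2;...>` with
#' 1-based tryptophan positions, chosen to be bit-stable for golden-file
#' comparisons.
#'
#' @param entries Output of [substitute_tryptophans()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_substitution_db <- function(entries, path) {
  headers <- paste0("sub|", entries$source_accession, "|W2", entries$target,
                    " POS=", vapply(entries$w_positions, paste,
                                    character(1), collapse = ";"))
  set <- Biostrings::AAStringSet(entries$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' NCBI translation table 1; translation stops before the first stop
#' codon (TAA/TAG/TGA) and a trailing incomplete codon is ignored.
#'
#' @param cds Nucleotide string over A/C/G/T.
#' @param frame_offset 0, 1 or 2 nucleotides skipped before the first
#'   codon (applied after `start_nt`).
#' @param start_nt 1-based nucleotide at which to start reading.
#' @return The translated residue string (possibly empty).
#' @export
#' @examples
#' translate_cds("ATGTGGAAA")            # "MWK"
#' translate_cds("ATGTGGAAATAG", frame_offset = 1, start_nt = 4)  # "GN"
translate_cds <- function(cds, frame_offset = 0L, start_nt = 1L) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]*$", cds)) {
    stop("CDS contains invalid nucleotide(s)", call. = FALSE)
  }
  stopifnot(frame_offset %in% 0:2, start_nt >= 1L)
  from <- start_nt + frame_offset
  if (from > nchar(cds)) return("")
  region <- substr(cds, from, nchar(cds))
  n_codons <- nchar(region) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(region, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Reporter construct specification
#'
#' Describes a reporter CDS carrying one tryptophan codon of interest
#' (the construct the decoding assays are built around). Validates that
#' the codon at `w_index` is TGG and records the in-frame translation.
#'
#' @param cds Nucleotide coding sequence (A/C/G/T).
#' @param w_index 1-based residue index of the tryptophan of interest.
#' @return A list of class `reporter_spec` with elements `cds`, `protein`
#'   and `w_index`.
#' @export
reporter_spec <- function(cds, w_index) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds)) {
    stop("CDS contains invalid nucleotide(s)", call. = FALSE)
  }
  w_index <- as.integer(w_index)
  codon <- substr(cds, 3L * (w_index - 1L) + 1L, 3L * w_index)
  if (!identical(codon, "TGG")) {
    stop("codon at residue ", w_index, " is '", codon,
         "', expected the tryptophan codon TGG", call. = FALSE)
  }
  protein <- translate_cds(cds)
  if (nchar(protein) < w_index) {
    stop("in-frame translation terminates before residue ", w_index,
         call. = FALSE)
  }
  structure(list(cds = cds, protein = protein, w_index = w_index),
            class = "reporter_spec")
}

#' +1 frameshift product at the tryptophan codon
#'
#' In-frame residues up to (but excluding) the tryptophan, then the +1
#' frame read from the second nucleotide of the W codon until the first
#' stop codon in that frame (or the end of the sequence).
#'
#' @param spec A [reporter_spec()].
#' @return Residue string of the frameshift product.
#' @export
frameshift_product <- function(spec) {
  stopifnot(inherits(spec, "reporter_spec"))
  prefix <- substr(spec$protein, 1L, spec$w_index - 1L)
  shift_from <- 3L * (spec$w_index - 1L) + 2L   # 2nd nt of the W codon
  paste0(prefix, translate_cds(spec$cds, start_nt = shift_from))
}

#' Single-site saturation variants of a peptide
#'
#' Every position replaced by every other residue: `nchar(peptide) * 19`
#' variants, each at Hamming distance 1 from the input.
#'
#' @param peptide Residue string.
#' @return Tibble with columns `position`, `from`, `to`, `sequence`.
#' @export
saturation_peptides <- function(peptide) {
  assert_peptide(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  grid <- tidyr::expand_grid(position = seq_along(chars), to = aa_alphabet())
  grid$from <- chars[grid$position]
  grid <- grid[grid$to != grid$from, ]
  grid$sequence <- purrr::map2_chr(grid$position, grid$to, function(p, t) {
    v <- chars; v[p] <- t; paste(v, collapse = "")
  })
  grid[, c("position", "from", "to", "sequence")]
}

#' Single-site saturation of one residue type across a protein
#'
#' For every occurrence of `residue` and every alternative amino acid
#' (19), one entry substituted at that single site only. Used for the
#' control databases that saturate phenylalanines or tyrosines of a
#' reporter protein.
#'
#' @param protein Residue string.
#' @param residue The residue type to saturate (e.g. `"F"` or `"Y"`).
#' @return Tibble with columns `position`, `from`, `to`, `sequence`;
#'   empty (with a warning) when `residue` is absent.
#' @export
residue_saturation_db <- function(protein, residue) {
  assert_peptide(protein, "protein")
  stopifnot(residue %in% aa_alphabet())
  pos <- as.integer(gregexpr(residue, protein, fixed = TRUE)[[1]])
  if (pos[1] == -1L) {
    warning("residue '", residue, "' absent from protein; empty database",
            call. = FALSE)
    return(tibble::tibble(position = integer(), from = character(),
                          to = character(), sequence = character()))
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  grid <- tidyr::expand_grid(position = pos,
                             to = setdiff(aa_alphabet(), residue))
  grid$from <- residue
  grid$sequence <- purrr::map2_chr(grid$position, grid$to, function(p, t) {
    v <- chars; v[p] <- t; paste(v, collapse = "")
  })
  grid[, c("position", "from", "to", "sequence")]
}

#' Translational bypass products of a reporter
#'
#' Two candidate products of the ribosome skipping the hungry tryptophan
#' codon: the deletion variant (protein with the W residue excised) and
#' the product of translation re-starting at the first in-frame GAA codon
#' strictly downstream of the W codon, read to the first stop.
#'
#' @param spec A [reporter_spec()].
#' @return List with `deletion_variant` and `gaa_restart_variant`
#'   residue strings (the latter empty, with a warning, when no
#'   downstream in-frame GAA exists).
#' @export
bypass_products <- function(spec) {
  stopifnot(inherits(spec, "reporter_spec"))
  chars <- strsplit(spec$protein, "", fixed = TRUE)[[1]]
  deletion <- paste(chars[-spec$w_index], collapse = "")

  n_codons <- nchar(spec$cds) %/% 3L
  restart <- ""
  if (n_codons > spec$w_index) {
    starts <- seq(3L * spec$w_index + 1L, by = 3L,
                  length.out = n_codons - spec$w_index)
    codons <- substring(spec$cds, starts, starts + 2L)
    hit <- match("GAA", codons)
    if (!is.na(hit)) {
      restart <- translate_cds(spec$cds, start_nt = starts[hit])
    }
  }
  if (!nzchar(restart)) {
    warning("no in-frame GAA codon downstream of the W codon; ",
            "empty restart variant", call. = FALSE)
  }
  list(deletion_variant = deletion, gaa_restart_variant = restart)
}

#' Build the five reporter search databases
#'
#' Covers the possible aberrant products of a single-tryptophan reporter:
#' \describe{
#'   \item{db1_inframe}{in-frame protein, +1 frameshift product, the
#'     in-frame protein with the W replaced by each of the 19 other
#'     residues, and the W-skipped protein (22 entries).}
#'   \item{db2_peptide_saturation}{every single-residue variant of the
#'     tryptic peptide spanning the W codon.}
#'   \item{db3_f_saturation}{single-site saturation of every
#'     phenylalanine in the in-frame protein.}
#'   \item{db4_y_saturation}{the tyrosine analogue of db3.}
#'   \item{db5_bypass}{tryptic peptides arising from exclusion of the W
#'     residue, plus the GAA-restart product.}
#' }
#'
#' @param spec A [reporter_spec()].
#' @param tryptic_w_peptide The in-frame tryptic peptide spanning the W
#'   codon; computed by [digest()] (0 missed cleavages, no length/mass
#'   filter) when `NULL`.
#' @param config Digest configuration for db5 peptides.
#' @return Named list of five tibbles with columns `name`, `sequence`.
#' @export
build_reporter_databases <- function(spec, tryptic_w_peptide = NULL,
                                     config = digest_config()) {
  stopifnot(inherits(spec, "reporter_spec"))
  protein <- spec$protein
  w <- spec$w_index

  if (is.null(tryptic_w_peptide)) {
    open <- digest_config(max_missed_cleavages = 0L, min_length = 1L,
                          max_length = 10000L, min_mass = 0,
                          max_mass = Inf,
                          proline_rule = config$proline_rule)
    peps <- digest_sequence(protein, open)
    hit <- peps[peps$start <= w & peps$end >= w, ]
    if (nrow(hit) == 0L) stop("no tryptic peptide spans the W codon",
                              call. = FALSE)
    tryptic_w_peptide <- hit$sequence[1]
  }

  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  w_repl <- vapply(setdiff(aa_alphabet(), "W"), function(t) {
    v <- chars; v[w] <- t; paste(v, collapse = "")
  }, character(1))
  bypass <- bypass_products(spec)
  db1 <- tibble::tibble(
    name = c("inframe", "frameshift_plus1",
             paste0("W", w, names(w_repl)), paste0("W", w, "skip")),
    sequence = c(protein, frameshift_product(spec), unname(w_repl),
                 bypass$deletion_variant)
  )

  sat <- saturation_peptides(tryptic_w_peptide)
  db2 <- tibble::tibble(
    name = paste0("pep_", sat$from, sat$position, sat$to),
    sequence = sat$sequence
  )

  f_sat <- residue_saturation_db(protein, "F")
  db3 <- tibble::tibble(
    name = if (nrow(f_sat)) paste0("F", f_sat$position, f_sat$to) else character(),
    sequence = f_sat$sequence
  )
  y_sat <- residue_saturation_db(protein, "Y")
  db4 <- tibble::tibble(
    name = if (nrow(y_sat)) paste0("Y", y_sat$position, y_sat$to) else character(),
    sequence = y_sat$sequence
  )

  # db5: tryptic peptides of the deletion variant spanning the excision
  # junction (residues w-1..w of the shortened protein), plus the
  # GAA-restart product
  del <- bypass$deletion_variant
  del_peps <- digest_sequence(del, config)
  junction <- del_peps[del_peps$start <= max(w - 1L, 1L) &
                         del_peps$end >= min(w, nchar(del)), ]
  db5 <- tibble::tibble(
    name = c(paste0("bypass_del_", junction$start, "_", junction$end),
             if (nzchar(bypass$gaa_restart_variant)) "bypass_gaa_restart"),
    sequence = c(junction$sequence,
                 if (nzchar(bypass$gaa_restart_variant))
                   bypass$gaa_restart_variant)
  )

  list(db1_inframe = db1, db2_peptide_saturation = db2,
       db3_f_saturation = db3, db4_y_saturation = db4, db5_bypass = db5)
}
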