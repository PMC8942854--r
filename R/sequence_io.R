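# Readers and writers for the standard formats the pipeline touches:
# FASTA proteomes and search databases, GMT gene sets, and the tabular
# evidence / annotation / expression files. All tabular I/O is UTF-8,
# tab-separated, with a header row and '.' as the decimal point.

#' Read a protein FASTA file into a tibble of validated records
#'
#' Accepts UniProt-style headers (`>sp|ACC|NAME ... GN=SYMBOL`) as well as
#' bare `>ACC` headers. The accession is the second pipe-delimited field
#' when pipes are present, otherwise the first whitespace token; the gene
#' symbol is parsed from a `GN=` token when present and empty otherwise.
#' Sequences are whitespace-stripped, uppercased and validated against the
#' 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param skip_invalid If `TRUE`, records containing non-canonical
#'   residues (B, J, O, U, X, Z, ...) are dropped with a warning instead
#'   of raising an error.
#' @return A tibble with columns `accession`, `gene`, `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|X GN=G1", "MKW"), f)
#' read_fasta(f)
read_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw_lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(raw_lines)))
  if (length(nonblank) == 0L) {
    return(tibble::tibble(accession = character(), gene = character(),
                          sequence = character()))
  }
  if (!startsWith(trimws(raw_lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " precedes any '>' header", call. = FALSE)
  }
  empty_headers <- nonblank[trimws(raw_lines[nonblank]) == ">"]
  if (length(empty_headers) > 0L) {
    stop("malformed FASTA: empty header at line ", empty_headers[1],
         call. = FALSE)
  }

  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  sequence <- unname(toupper(gsub("\\s", "", as.character(seqs))))

  accession <- vapply(headers, function(h) {
    if (grepl("|", h, fixed = TRUE)) {
      strsplit(h, "|", fixed = TRUE)[[1]][2]
    } else {
      strsplit(trimws(h), "\\s+")[[1]][1]
    }
  }, character(1), USE.NAMES = FALSE)
  gene <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  gene[is.na(gene)] <- ""

  records <- tibble::tibble(accession = accession, gene = gene,
                            sequence = sequence)
  bad <- invalid_residues(records$sequence)
  if (any(bad)) {
    offenders <- records$accession[bad]
    chars <- vapply(records$sequence[bad], function(s) {
      ch <- first_bad_char(s)
      if (is.na(ch)) "<empty>" else ch
    }, character(1), USE.NAMES = FALSE)
    msg <- paste0(offenders, " ('", chars, "')", collapse = ", ")
    if (skip_invalid) {
      warning("dropping ", sum(bad), " record(s) with non-canonical residues: ",
              msg, call. = FALSE)
      records <- records[!bad, ]
    } else {
      stop("non-canonical residue in ", msg,
           "; use skip_invalid = TRUE to drop such records", call. = FALSE)
    }
  }
  if (anyDuplicated(records$accession)) {
    dup <- unique(records$accession[duplicated(records$accession)])
    stop("duplicate accession(s) in FASTA: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  records
}

#' Write protein records to FASTA
#'
#' Headers are `>ACC GN=SYMBOL` (the `GN=` token omitted for records with
#' an empty gene), so `read_fasta(write_fasta(x))` round-trips exactly.
#'
#' @param records Tibble with `accession`, `sequence` and optionally
#'   `gene` columns.
#' @param path Output path.
#' @param width Line width for the sequence block.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("accession", "sequence") %in% names(records)))
  gene <- if ("gene" %in% names(records)) records$gene else
    rep("", nrow(records))
  headers <- ifelse(nzchar(gene),
                    paste0(records$accession, " GN=", gene),
                    records$accession)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Column mapping for peptide evidence tables
#'
#' Search-engine peptide reports differ only in column naming; this thin
#' mapping adapts them to the canonical evidence shape without bespoke
#' per-engine readers.
#'
#' @param peptide,protein,sample,replicate,condition,log_intensity Column
#'   names in the input file holding the corresponding field.
#' @return A named list used by [read_evidence_table()].
#' @export
evidence_columns <- function(peptide = "peptide", protein = "protein",
                             sample = "sample", replicate = "replicate",
                             condition = "condition",
                             log_intensity = "log_intensity") {
  list(peptide = peptide, protein = protein, sample = sample,
       replicate = replicate, condition = condition,
       log_intensity = log_intensity)
}

#' Read a peptide evidence table
#'
#' One row per detected peptide per sample/replicate, with a
#' reference-channel-normalized log2 intensity (the shape of isobaric
#' quantification peptide reports). Rows with an empty intensity cell are
#' retained but flagged `detected = FALSE`.
#'
#' @param path Path to a TSV file with a header row.
#' @param columns Column mapping, see [evidence_columns()].
#' @return Tibble with columns `peptide`, `protein`, `sample_id`,
#'   `replicate_id`, `condition`, `log_intensity`, `detected`.
#' @export
read_evidence_table <- function(path, columns = evidence_columns()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(unlist(columns), names(tab))
  if (length(missing) > 0L) {
    stop("evidence table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::tibble(
    peptide = toupper(tab[[columns$peptide]]),
    protein = tab[[columns$protein]],
    sample_id = tab[[columns$sample]],
    replicate_id = tab[[columns$replicate]],
    condition = tab[[columns$condition]],
    log_intensity = suppressWarnings(as.numeric(tab[[columns$log_intensity]]))
  )
  ev$detected <- !is.na(ev$log_intensity)
  bad <- is.na(ev$peptide) | !nzchar(ev$peptide) | invalid_residues(ev$peptide)
  if (any(bad)) {
    stop("invalid peptide sequence(s) in evidence rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  key <- paste(ev$peptide, ev$sample_id, ev$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (peptide, sample, replicate) row(s): ",
         paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = "; "),
         call. = FALSE)
  }
  ev
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then tab-separated gene symbols.
#' Duplicate symbols within a line are deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `name`, `description` and list-column
#'   `genes` (character vectors).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- purrr::map(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene symbol(s) in set '", f[1],
              "' deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    list(name = f[1], description = f[2], genes = genes)
  })
  tibble::tibble(
    name = purrr::map_chr(sets, "name"),
    description = purrr::map_chr(sets, "description"),
    genes = purrr::map(sets, "genes")
  )
}

#' Read a per-sample cohort annotation table
#'
#' Expected columns: `sample_id`, `tissue` (levels `tumour` / `normal`;
#' the spelling `tumor` is accepted and normalized), `ido1_log_intensity`
#' (log2, reference-normalized) and optionally `cohort`.
#'
#' @param path Path to a TSV file.
#' @return Tibble with the validated annotation.
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "tissue", "ido1_log_intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("annotation is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann <- tibble::tibble(
    sample_id = tab$sample_id,
    tissue = ifelse(tab$tissue == "tumor", "tumour", tab$tissue),
    ido1_log_intensity = as.numeric(tab$ido1_log_intensity),
    cohort = if ("cohort" %in% names(tab)) tab$cohort else ""
  )
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id(s) in annotation", call. = FALSE)
  }
  bad <- !ann$tissue %in% c("tumour", "normal")
  if (any(bad)) {
    stop("tissue must be 'tumour' or 'normal'; offending sample(s): ",
         paste(ann$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  ann
}

#' Read a gene-by-sample expression matrix
#'
#' First column: gene symbol; remaining columns: per-sample log2
#' intensities (reference-normalized, so 0 is the natural high/low
#' boundary).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2L) stop("expression matrix needs >= 2 columns", call. = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix",
                                 call. = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  mat
}

#' Write a gene-by-sample expression matrix (inverse of
#' [read_expression_matrix()])
#' @param mat Numeric matrix with gene rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
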