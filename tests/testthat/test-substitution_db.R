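test_that("tryptophan substitution replaces all sites simultaneously", {
  prot <- tibble::tibble(accession = c("P1", "P2", "P3"), gene = "",
                         sequence = c("MAWK", "MAAK", "MWGWR"))
  f_only <- substitute_tryptophans(prot, targets = "F")
  expect_equal(f_only$source_accession, c("P1", "P3"))
  expect_equal(f_only$sequence, c("MAFK", "MFGFR"))
  expect_equal(f_only$w_positions, list(3L, c(2L, 4L)))

  a_only <- substitute_tryptophans(prot, targets = "A")
  expect_equal(a_only$sequence[a_only$source_accession == "P3"], "MAGAR")
})

test_that("default policy yields 17 variants per W-containing protein", {
  prot <- tibble::tibble(accession = "P1", gene = "", sequence = "MAWK")
  entries <- substitute_tryptophans(prot)
  expect_equal(nrow(entries), 17L)
  expect_false(any(c("W", "K", "R") %in% entries$target))
})

test_that("invalid target sets are configuration errors", {
  prot <- tibble::tibble(accession = "P1", gene = "", sequence = "MAWK")
  expect_error(substitute_tryptophans(prot, targets = character(0)),
               "non-empty")
  expect_error(substitute_tryptophans(prot, targets = c("F", "W")), "W")
  expect_error(substitute_tryptophans(prot, targets = "Z"), "invalid")
})

test_that("substituted entries preserve length, remove W, and are idempotent", {
  set.seed(5)
  prot <- tibble::tibble(
    accession = sprintf("R%02d", 1:15), gene = "",
    sequence = vapply(1:15, function(i)
      random_protein(sample(30:120, 1)), character(1)))
  entries <- substitute_tryptophans(prot)
  src_len <- nchar(prot$sequence[match(entries$source_accession,
                                       prot$accession)])
  expect_equal(nchar(entries$sequence), src_len)
  expect_false(any(grepl("W", entries$sequence, fixed = TRUE)))
  for (i in seq_len(nrow(entries))) {
    w <- entries$w_positions[[i]]
    src <- prot$sequence[prot$accession == entries$source_accession[i]]
    expect_equal(unique(substring(src, w, w)), "W")
    expect_equal(unique(substring(entries$sequence[i], w, w)),
                 entries$target[i])
  }
  resub <- substitute_tryptophans(
    tibble::tibble(accession = paste0("E", seq_len(nrow(entries))),
                   gene = "", sequence = entries$sequence))
  expect_equal(nrow(resub), 0L)
})

test_that("CDS translation follows the standard code with stop/trailing rules", {
  expect_equal(translate_cds("ATGTGGAAA"), "MWK")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGTGGAAATAG", frame_offset = 1, start_nt = 4),
               "GN")
  expect_equal(translate_cds(""), "")
  expect_error(translate_cds("ATGN"), "nucleotide")
})

test_that("translation agrees with the Biostrings codon-table oracle", {
  set.seed(21)
  for (i in 1:300) {
    n <- 3L * sample(1:40, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE))
    oracle <- sub("\\*.*$", "", oracle)
    expect_equal(translate_cds(cds), oracle, info = cds)
  }
})

test_that("frameshift product switches to +1 at the W codon", {
  expect_equal(frameshift_product(reporter_spec("ATGTGGAAATAG", 2)), "MGN")
  expect_equal(frameshift_product(reporter_spec("ATGTGGTAG", 2)), "MG")
  expect_error(reporter_spec("ATGTTTAAA", 2), "TGG")
})

test_that("saturation variants cover every position and residue once", {
  sat <- saturation_peptides("AW")
  expect_equal(nrow(sat), 38L)
  sat1 <- saturation_peptides("A")
  expect_equal(nrow(sat1), 19L)
  expect_false("A" %in% sat1$sequence)
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  pep <- "MKWAR"
  satp <- saturation_peptides(pep)
  expect_equal(nrow(satp), 5L * 19L)
  expect_true(all(vapply(satp$sequence, hamming, numeric(1), a = pep) == 1))
  expect_error(saturation_peptides(""), "non-empty")
})

test_that("single-residue-type saturation emits 19 entries per occurrence", {
  expect_equal(nrow(residue_saturation_db("AFA", "F")), 19L)
  db <- residue_saturation_db("AFAF", "F")
  expect_equal(nrow(db), 38L)
  expect_true(all(mapply(function(s, p) substr(s, p, p) != "F",
                         db$sequence, db$position)))
  expect_warning(empty <- residue_saturation_db("AAA", "F"), "absent")
  expect_equal(nrow(empty), 0L)
})

test_that("bypass products include W deletion and GAA restart", {
  spec <- reporter_spec("ATGAAATGGGCTCGTTAA", 3)   # MKWAR
  expect_warning(bp <- bypass_products(spec), "GAA")
  expect_equal(bp$deletion_variant, "MKAR")

  spec2 <- reporter_spec("ATGTGGGAAAAATAG", 2)     # M W E K *
  bp2 <- bypass_products(spec2)
  expect_equal(bp2$gaa_restart_variant, "EK")
})

test_that("the five reporter databases have the expected structure", {
  cds <- paste(readLines(system.file("extdata",
                                     "synthetic_reporter_cds.fasta",
                                     package = "substiscan"))[-1],
               collapse = "")
  spec <- reporter_spec(cds, 17)
  dbs <- build_reporter_databases(spec)
  expect_named(dbs, c("db1_inframe", "db2_peptide_saturation",
                      "db3_f_saturation", "db4_y_saturation", "db5_bypass"))
  expect_equal(nrow(dbs$db1_inframe), 22L)   # 1 + 1 + 19 + 1
  expect_false(any(grepl("W", dbs$db1_inframe$sequence[
    grepl("^W17", dbs$db1_inframe$name)], fixed = TRUE)))
  # db2 saturates the tryptic W-spanning peptide (the R-P bond upstream
  # is protected by the proline rule): |pep| x 19 entries
  w_pep <- "GEYVLNWAEQSTRPFMGHK"
  expect_equal(substring(spec$protein, 11, 29), w_pep)
  expect_equal(nrow(dbs$db2_peptide_saturation), nchar(w_pep) * 19L)
  n_f <- lengths(gregexpr("F", spec$protein, fixed = TRUE))
  expect_equal(nrow(dbs$db3_f_saturation), n_f * 19L)
  expect_gt(nrow(dbs$db5_bypass), 0L)
})

test_that("toy spec without F yields an empty db3 with a warning", {
  # MKWEK*: no phenylalanine (and no tyrosine) anywhere
  spec <- reporter_spec("ATGAAATGGGAAAAATAG", 3)
  w <- capture_warnings(dbs <- build_reporter_databases(spec))
  expect_match(w, "absent", all = TRUE)
  expect_equal(nrow(dbs$db3_f_saturation), 0L)
  expect_equal(nrow(dbs$db4_y_saturation), 0L)
})
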