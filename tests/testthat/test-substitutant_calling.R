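# P1 = MKAAAWAARDDDDDDK carries the W site at position 6; its W>F
# peptide AAAFAAR is, by construction, also a canonical substring of P2
# = MKYYYYYYRAAAFAARK, which exercises the uniqueness filter.

test_that("peptides classify as canonical, substitutant or unmapped", {
  prot <- toy_proteome()
  entries <- substitute_tryptophans(prot)

  res <- map_peptide_to_sites("AAALAAR", prot, entries)
  expect_equal(res$class, "substitutant")
  expect_equal(res$matches$accession, "P1")
  expect_equal(res$matches$target, "L")
  expect_equal(res$matches$sites[[1]], 6L)

  # W>F peptide collides with canonical P2 sequence: rejected
  expect_equal(map_peptide_to_sites("AAAFAAR", prot, entries)$class,
               "canonical")
  expect_equal(map_peptide_to_sites("MKAAAWAAR", prot, entries)$class,
               "canonical")
  expect_equal(map_peptide_to_sites("GGGGGGG", prot, entries)$class,
               "unmapped")
})

test_that("identical peptides from different proteins are ambiguous", {
  prot <- tibble::tibble(accession = c("Q1", "Q2"), gene = "",
                         sequence = c("MKAAAWAAR", "GGGKAAAWAARGGG"))
  entries <- substitute_tryptophans(prot, targets = c("F", "L"))
  expect_equal(map_peptide_to_sites("AAAFAAR", prot, entries)$class,
               "ambiguous")
  idx <- peptide_index(prot, entries)
  expect_equal(idx$class[idx$peptide == "AAAFAAR"], "ambiguous")
})

test_that("positivity and reproducibility filters gate call emission", {
  prot <- toy_proteome()
  entries <- substitute_tryptophans(prot)
  idx <- peptide_index(prot, entries)

  ev <- toy_evidence(rep("AAALAAR", 2), "s1", c("r1", "r2"), "IFN",
                     c(1.2, 0.8))
  calls <- call_substitutants(ev, index = idx)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$accession, "P1")
  expect_equal(calls$to_residue, "L")
  expect_equal(calls$sites[[1]], 6L)
  expect_equal(calls$replicates_detected[[1]], c(IFN = 2L))
  expect_true(calls$isobaric_pair)

  one_rep <- call_substitutants(ev[1, ], index = idx)
  expect_equal(nrow(one_rep), 0L)

  # exactly 0 is not positive (strict >)
  at_zero <- toy_evidence(rep("AAALAAR", 2), "s1", c("r1", "r2"), "IFN",
                          c(0.0, 0.8))
  expect_equal(nrow(call_substitutants(at_zero, index = idx)), 0L)
  expect_equal(nrow(call_substitutants(
    at_zero, index = idx,
    config = call_filter_config(positivity_threshold = -0.5))), 1L)
})

test_that("canonical-substring peptides never yield calls by default", {
  prot <- toy_proteome()
  entries <- substitute_tryptophans(prot)
  idx <- peptide_index(prot, entries)
  ev <- toy_evidence(rep("AAAFAAR", 2), "s1", c("r1", "r2"), "IFN",
                     c(2.0, 2.0))
  expect_equal(nrow(call_substitutants(ev, index = idx)), 0L)
  loose <- call_substitutants(
    ev, index = idx,
    config = call_filter_config(require_unique_vs_canonical = FALSE))
  expect_equal(nrow(loose), 1L)
})

test_that("evidence with unannotated samples is rejected", {
  prot <- toy_proteome()
  idx <- peptide_index(prot, substitute_tryptophans(prot))
  ev <- toy_evidence("AAALAAR", "ghost", "r1", "IFN", 1)
  ann <- tibble::tibble(sample_id = "s1", tissue = "tumour",
                        ido1_log_intensity = 0.5, cohort = "")
  expect_error(call_substitutants(ev, index = idx, annotation = ann),
               "ghost")
})

test_that("condition partition counts specific and shared calls", {
  prot <- toy_proteome()
  idx <- peptide_index(prot, substitute_tryptophans(prot))
  # L call in both conditions, M call only in IFN, N call only in Ctrl
  ev <- dplyr::bind_rows(
    toy_evidence(rep("AAALAAR", 4), c("s1", "s1", "s2", "s2"),
                 c("r1", "r2", "r1", "r2"),
                 c("IFN", "IFN", "Ctrl", "Ctrl"), 1),
    toy_evidence(rep("AAAMAAR", 2), "s1", c("r1", "r2"), "IFN", 1),
    toy_evidence(rep("AAANAAR", 2), "s2", c("r1", "r2"), "Ctrl", 1))
  calls <- call_substitutants(ev, index = idx)
  part <- condition_partition(calls, "IFN", "Ctrl")
  expect_equal(part, c(only_a = 1L, only_b = 1L, both = 1L))
  expect_equal(sum(part), nrow(calls))
  expect_error(condition_partition(calls, "IFN", "nosuch"), "unknown")
  empty <- call_substitutants(ev[0, ], index = idx)
  expect_equal(condition_partition(empty, "IFN", "Ctrl"),
               c(only_a = 0L, only_b = 0L, both = 0L))
})

test_that("partition counts always sum to qualifying calls on random data", {
  prot <- toy_proteome()
  idx <- peptide_index(prot, substitute_tryptophans(prot))
  peps <- idx$peptide[idx$class == "substitutant"]
  set.seed(53)
  for (rep in 1:5) {
    ev <- tidyr::expand_grid(peptide = sample(peps, 6),
                             sample_id = c("s1", "s2"),
                             replicate_id = c("r1", "r2"))
    ev$condition <- ifelse(ev$sample_id == "s1", "A", "B")
    ev$log_intensity <- rnorm(nrow(ev), 0.5, 1)
    ev$protein <- ""
    ev$detected <- TRUE
    ev <- ev[runif(nrow(ev)) < 0.8, ]
    calls <- call_substitutants(ev, index = idx)
    part <- condition_partition(calls, "A", "B")
    in_a <- vapply(calls$replicates_detected,
                   function(r) isTRUE(r["A"] >= 2), logical(1))
    in_b <- vapply(calls$replicates_detected,
                   function(r) isTRUE(r["B"] >= 2), logical(1))
    expect_equal(unname(sum(part)), sum(in_a | in_b))
  }
})

test_that("noiseless planted simulation is recovered perfectly", {
  cfg <- noiseless_config(seed = 3)
  prot <- simulate_proteome(cfg)
  sim <- simulate_cohort(prot, cfg)
  calls <- call_substitutants(sim$evidence, index = sim$prep$index,
                              annotation = sim$annotation)
  rec <- evaluate_recovery(calls, sim$truth)
  expect_true(all(rec$precision == 1))
  expect_true(all(rec$recall == 1))
})

test_that("tightening filters is monotone in the number of calls", {
  cfg <- small_sim_config(seed = 5)
  prot <- simulate_proteome(cfg)
  sim <- simulate_cohort(prot, cfg)
  idx <- sim$prep$index
  n_calls <- function(threshold, reps) nrow(call_substitutants(
    sim$evidence, index = idx,
    config = call_filter_config(positivity_threshold = threshold,
                                min_replicates = reps)))
  by_thr <- vapply(c(-1, 0, 0.5, 1, 2), n_calls, numeric(1), reps = 2L)
  expect_true(all(diff(by_thr) <= 0))
  by_reps <- vapply(1:4, function(r) n_calls(0, r), numeric(1))
  expect_true(all(diff(by_reps) <= 0))
})

test_that("no emitted call is a canonical substring; output is deterministic", {
  cfg <- small_sim_config(seed = 8)
  prot <- simulate_proteome(cfg)
  sim <- simulate_cohort(prot, cfg)
  calls <- call_substitutants(sim$evidence, index = sim$prep$index)
  canon <- paste(prot$sequence, collapse = "#")
  expect_false(any(stringr::str_detect(canon,
                                       stringr::fixed(calls$peptide))))
  again <- call_substitutants(sim$evidence, index = sim$prep$index)
  expect_identical(calls, again)
})

test_that("planted W>F loci are recovered with high recall, no false calls", {
  # background off: the sub-threshold canonical peptides are the noise
  cfg0 <- small_sim_config(seed = 1, background_rate = 0)
  prot <- simulate_proteome(cfg0)
  prep <- prepare_simulation(prot)
  for (s in 1:20) {
    cfg <- small_sim_config(seed = 100 + s, background_rate = 0)
    sim <- simulate_cohort(prot, cfg, prep = prep)
    calls <- call_substitutants(sim$evidence, index = prep$index)
    rec <- evaluate_recovery(calls, sim$truth)
    expect_true(all(rec$precision == 1))
    expect_true(all(rec$recall[rec$target == "F"] >= 0.95))
  }
})
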