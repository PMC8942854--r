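# Weighted Kolmogorov-Smirnov gene-set enrichment with a seeded
# gene-label permutation null.

# running-sum statistic on a ranked metric vector; hits given as a
# logical mask aligned with the (already ordered) metrics
gsea_running_sum <- function(metric_sorted, hit_mask, weight_exponent) {
  n <- length(metric_sorted)
  n_hit <- sum(hit_mask)
  w <- abs(metric_sorted)^weight_exponent
  w_hit_total <- sum(w[hit_mask])
  step <- numeric(n)
  if (w_hit_total > 0) {
    step[hit_mask] <- w[hit_mask] / w_hit_total
  } else {
    # all hit weights zero (e.g. metric 0 at every hit): fall back to
    # unweighted increments so the statistic stays defined
    step[hit_mask] <- 1 / n_hit
  }
  step[!hit_mask] <- -1 / (n - n_hit)
  cumsum(step)
}

#' Gene-set enrichment score with permutation null
#'
#' Genes are ranked by the metric in decreasing order (ties broken by
#' gene symbol for determinism). The running sum increments by
#' `|metric|^p` (normalized over the hits) at each gene-set member and
#' decrements by `1/(N - N_hits)` at each miss; the enrichment score
#' (ES) is the signed maximum deviation from zero. The null is built by
#' permuting gene labels (`n_permutations` draws of random hit sets of
#' the same size); NES divides the ES by the mean |null ES| of matching
#' sign, and the two-sided empirical p-value compares |ES| against the
#' |null ES| distribution with add-one smoothing, so
#' p >= 1/(n_permutations + 1).
#'
#' @param ranking Named numeric vector: gene -> ranking metric (for the
#'   substitutant analysis, `delta` from [per_gene_high_low_counts()]).
#' @param gene_set Character vector of gene symbols (or a one-row slice
#'   of [read_gene_sets()]).
#' @param weight_exponent Hit-weight exponent p (default 1).
#' @param n_permutations Permutation count (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `gsea_result`: `gene_set`, `es`, `nes`,
#'   `p_value`, `n_permutations`, `seed`, `leading_edge` and the running
#'   sum `trace` (tibble with `rank`, `gene`, `metric`, `hit`,
#'   `running_sum`) for plotting.
#' @export
gsea_score <- function(ranking, gene_set, weight_exponent = 1,
                       n_permutations = 1000L, seed = 1L) {
  set_name <- "gene_set"
  if (is.data.frame(gene_set)) {
    stopifnot(nrow(gene_set) == 1L)
    set_name <- gene_set$name
    gene_set <- gene_set$genes[[1]]
  }
  if (is.null(names(ranking)) || anyDuplicated(names(ranking))) {
    stop("ranking must be a named numeric vector with unique gene names",
         call. = FALSE)
  }
  ord <- order(-ranking, names(ranking))
  metric <- unname(ranking[ord])
  genes <- names(ranking)[ord]
  hit <- genes %in% gene_set
  n <- length(genes)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has empty intersection with the ranking",
                        call. = FALSE)
  if (n_hit == n) stop("gene set covers the whole ranking (no misses)",
                       call. = FALSE)

  running <- gsea_running_sum(metric, hit, weight_exponent)
  es <- running[which.max(abs(running))]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  null_es <- vapply(seq_len(n_permutations), function(b) {
    h <- logical(n)
    h[sample.int(n, n_hit)] <- TRUE
    r <- gsea_running_sum(metric, h, weight_exponent)
    r[which.max(abs(r))]
  }, numeric(1))

  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign) > 0L) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_permutations + 1)

  structure(list(
    gene_set = set_name, es = es, nes = nes, p_value = p,
    n_permutations = as.integer(n_permutations), seed = as.integer(seed),
    leading_edge = genes[hit & seq_len(n) <= which.max(abs(running))],
    trace = tibble::tibble(rank = seq_len(n), gene = genes,
                           metric = metric, hit = hit,
                           running_sum = running)
  ), class = "gsea_result")
}

#' GSEA over multiple gene sets with BH correction
#'
#' Runs [gsea_score()] for each set of a GMT table and adjusts the
#' empirical p-values across sets with Benjamini-Hochberg.
#'
#' @param ranking Named numeric vector, gene -> metric.
#' @param gene_sets Tibble from [read_gene_sets()].
#' @param ... Passed to [gsea_score()].
#' @return Tibble with columns `gene_set`, `es`, `nes`, `p_value`,
#'   `padj`.
#' @export
gsea_batch <- function(ranking, gene_sets, ...) {
  res <- purrr::map(seq_len(nrow(gene_sets)), function(i)
    gsea_score(ranking, gene_sets[i, ], ...))
  out <- tibble::tibble(
    gene_set = purrr::map_chr(res, "gene_set"),
    es = purrr::map_dbl(res, "es"),
    nes = purrr::map_dbl(res, "nes"),
    p_value = purrr::map_dbl(res, "p_value")
  )
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
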