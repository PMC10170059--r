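#' BestKeeper descriptive stability analysis
#'
#' Works directly on raw Ct values. Per gene it reports the arithmetic and
#' geometric mean, minimum, maximum, standard deviation SD(Ct) and
#' CV% = 100 * SD / mean. The BestKeeper index is the per-sample geometric
#' mean of Ct over all genes in the panel; each gene's Pearson correlation r
#' with the index (with a two-sided t-test p-value on n - 2 degrees of
#' freedom) measures how well it tracks the panel consensus.
#'
#' Ranking follows the tool's headline statistic: ascending SD(Ct), ties by
#' gene id. Genes with SD(Ct) > 1 are flagged inconsistent (conventionally
#' considered unacceptable as references). A gene with zero Ct variance has
#' an undefined r, reported as `NA` and ranked by SD alone.
#'
#' @param ct Wide Ct tibble, at least 2 genes and 3 samples, Ct > 0.
#' @return An object of class `ref_bestkeeper`: list with `ranking` (tibble
#'   of per-gene statistics, `r`, `p_value`, `inconsistent`, `rank`) and
#'   `index` (tibble `sample_id`, `index`).
#' @export
bestkeeper <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2) abort("BestKeeper needs at least 2 genes")
  if (ncol(m) < 3) abort("BestKeeper needs at least 3 samples")
  if (any(m <= 0)) abort("Ct must be > 0 for the geometric mean")
  n <- ncol(m)
  index <- apply(m, 2, geomean)
  stats <- tibble::tibble(
    gene_id = rownames(m),
    mean_ct = unname(rowMeans(m)),
    geo_mean_ct = unname(apply(m, 1, geomean)),
    min_ct = unname(apply(m, 1, min)),
    max_ct = unname(apply(m, 1, max)),
    sd_ct = unname(apply(m, 1, sd)),
    cv_pct = unname(100 * apply(m, 1, sd) / rowMeans(m))
  )
  r <- vapply(seq_len(nrow(m)), function(j) {
    if (sd(m[j, ]) == 0 || sd(index) == 0) NA_real_ else cor(m[j, ], index)
  }, numeric(1))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.nan(p)] <- 0 # |r| exactly 1
  ranking <- stats |>
    dplyr::mutate(r = r, p_value = p,
                  inconsistent = .data$sd_ct > 1,
                  rank = rank_avg(.data$sd_ct)) |>
    dplyr::arrange(.data$rank, .data$gene_id)
  structure(list(ranking = ranking,
                 index = tibble::tibble(sample_id = colnames(m), index = index)),
            class = "ref_bestkeeper")
}

#' @export
print.ref_bestkeeper <- function(x, ...) {
  cat("BestKeeper descriptive statistics (ranked by SD(Ct))\n")
  print(x$ranking, n = Inf)
  invisible(x)
}

#' @rdname bestkeeper
#' @param x A `ref_bestkeeper` object.
#' @param ... Unused.
#' @export
tidy.ref_bestkeeper <- function(x, ...) x$ranking
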