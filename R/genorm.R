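#' geNorm expression-stability analysis
#'
#' The geNorm M value of a gene is the arithmetic mean, over every other
#' gene in the panel, of the standard deviation across samples of the
#' pairwise log2 expression ratio. Because ratios of a stable pair are
#' constant across samples, low M means stable. Genes are then excluded one
#' at a time (highest M first, recomputing after each exclusion) until two
#' remain; these two cannot be ordered by the method and share ranks 1-2.
#'
#' The pairwise variation V(n -> n+1) is the standard deviation across
#' samples of log2(NF_n / NF_(n+1)), where NF_n is the per-sample geometric
#' mean of the relative quantities of the n most stable genes. V is
#' conventionally used to judge how many reference genes are needed; it is
#' reported here, not thresholded.
#'
#' @param q Wide tibble of relative quantities from [ct_to_quantity()]
#'   (all values > 0), with at least 3 genes and 2 samples.
#' @return An object of class `ref_genorm`: list with `ranking` (tibble
#'   `gene_id`, `m_value` from the first round, `rank` — last two tied at
#'   1.5), `exclusion_order`, `pairwise_variation` (tibble `n`, `v`), and
#'   `m_first_round`.
#' @export
genorm <- function(q) {
  m <- wide_to_matrix(q)
  if (nrow(m) < 3) abort("geNorm needs at least 3 genes")
  if (ncol(m) < 2) abort("geNorm needs at least 2 samples")
  if (any(!is.finite(m) | m <= 0)) abort("quantities must be finite and > 0")
  lg <- log2(m)

  m_first <- genorm_m(lg)
  excluded <- character(0)
  keep <- rownames(lg)
  # stepwise exclusion of the least stable gene; ties broken by the
  # lexicographically last id so reruns are reproducible
  while (length(keep) > 2) {
    mv <- genorm_m(lg[keep, , drop = FALSE])
    worst <- names(mv)[mv == max(mv)]
    worst <- sort(worst)[length(worst)]
    excluded <- c(excluded, worst)
    keep <- setdiff(keep, worst)
  }
  stability_order <- c(sort(keep), rev(excluded)) # most stable first
  rank_pos <- seq_along(stability_order)
  rank_pos[1:2] <- 1.5 # final pair is unordered by construction

  # V(n -> n+1) over normalization factors built from the top-n genes
  g <- nrow(lg)
  v <- vapply(2:(g - 1), function(n) {
    nf_n <- colMeans(lg[stability_order[1:n], , drop = FALSE])
    nf_n1 <- colMeans(lg[stability_order[1:(n + 1)], , drop = FALSE])
    sd(nf_n - nf_n1)
  }, numeric(1))

  ranking <- tibble::tibble(
    gene_id = stability_order,
    m_value = unname(m_first[stability_order]),
    rank = rank_pos
  )
  structure(list(
    ranking = ranking,
    exclusion_order = excluded,
    pairwise_variation = tibble::tibble(n = 2:(g - 1), v = v),
    m_first_round = tibble::tibble(gene_id = names(m_first),
                                   m_value = unname(m_first))
  ), class = "ref_genorm")
}

# M values for a log2-quantity matrix (genes x samples)
genorm_m <- function(lg) {
  g <- nrow(lg)
  out <- vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j), function(k) sd(lg[j, ] - lg[k, ]),
                numeric(1)))
  }, numeric(1))
  setNames(out, rownames(lg))
}

#' @export
print.ref_genorm <- function(x, ...) {
  cat("geNorm stability ranking (low M = stable)\n")
  print(x$ranking, n = Inf)
  invisible(x)
}

#' @rdname genorm
#' @param x A `ref_genorm` object.
#' @param ... Unused.
#' @export
tidy.ref_genorm <- function(x, ...) x$ranking
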