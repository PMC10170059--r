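#' Comparative delta-Ct stability analysis
#'
#' For every pair of genes the standard deviation across samples of their Ct
#' difference is computed; a gene's stability score is the mean of its
#' pairwise SDs against every other panel gene. If two genes maintain a
#' constant Ct offset in all samples their pairwise SD is zero, so low
#' scores indicate stable relative expression. Ranking is ascending.
#'
#' @param ct Wide Ct tibble, at least 2 genes and 2 samples. Genes with
#'   missing Ct are dropped with a warning (complete-case).
#' @return An object of class `ref_deltact`: list with `ranking` (tibble
#'   `gene_id`, `mean_pairwise_sd`, `rank`) and `pairwise_sd` (symmetric
#'   gene-by-gene matrix, zero diagonal).
#' @export
delta_ct <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2) abort("delta-Ct needs at least 2 genes")
  if (ncol(m) < 2) abort("delta-Ct needs at least 2 samples")
  g <- nrow(m)
  pw <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      pw[j, k] <- pw[k, j] <- sd(m[j, ] - m[k, ])
    }
  }
  score <- rowSums(pw) / (g - 1)
  ranking <- tibble::tibble(gene_id = rownames(m),
                            mean_pairwise_sd = unname(score)) |>
    dplyr::mutate(rank = rank_avg(.data$mean_pairwise_sd)) |>
    dplyr::arrange(.data$rank, .data$gene_id)
  structure(list(ranking = ranking, pairwise_sd = pw), class = "ref_deltact")
}

#' @export
print.ref_deltact <- function(x, ...) {
  cat("Delta-Ct stability ranking (mean pairwise SD; low = stable)\n")
  print(x$ranking, n = Inf)
  invisible(x)
}

#' @rdname delta_ct
#' @param x A `ref_deltact` object.
#' @param ... Unused.
#' @export
tidy.ref_deltact <- function(x, ...) x$ranking
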