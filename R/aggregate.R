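#' Comprehensive stability ranking by geometric mean of method ranks
#'
#' Combines the geNorm, NormFinder, BestKeeper and delta-Ct rankings into a
#' single order: each gene's four rank positions (average ranks where a
#' method ties genes; geNorm's final pair carries ranks 1.5/1.5) are reduced
#' to their geometric mean GM = (r1 r2 r3 r4)^(1/4), and genes are ordered
#' by ascending GM. Exact GM ties are broken by the delta-Ct rank, then by
#' gene id, so the final order is deterministic.
#'
#' @param genorm A `ref_genorm` object (or a tibble with `gene_id`, `rank`).
#' @param normfinder A `ref_normfinder` object (or rank tibble).
#' @param bestkeeper A `ref_bestkeeper` object (or rank tibble).
#' @param deltact A `ref_deltact` object (or rank tibble).
#' @return Tibble with columns `gene_id`, `rank_genorm`, `rank_normfinder`,
#'   `rank_bestkeeper`, `rank_deltact`, `geomean`, `final_rank`, ordered by
#'   `final_rank`.
#' @export
comprehensive_ranking <- function(genorm, normfinder, bestkeeper, deltact) {
  ranks <- list(genorm = genorm, normfinder = normfinder,
                bestkeeper = bestkeeper, deltact = deltact) |>
    purrr::map(extract_ranks)
  genes <- ranks[[1]]$gene_id
  for (nm in names(ranks)[-1]) {
    diff <- c(setdiff(genes, ranks[[nm]]$gene_id),
              setdiff(ranks[[nm]]$gene_id, genes))
    if (length(diff) > 0) {
      abort(sprintf("gene sets differ between methods (offenders: %s)",
                    paste(sort(unique(diff)), collapse = ", ")))
    }
  }
  tbl <- purrr::imap(ranks, ~ dplyr::rename(.x, !!paste0("rank_", .y) := "rank")) |>
    purrr::reduce(dplyr::inner_join, by = "gene_id")
  tbl |>
    dplyr::mutate(geomean = (.data$rank_genorm * .data$rank_normfinder *
                             .data$rank_bestkeeper * .data$rank_deltact)^(1 / 4)) |>
    dplyr::arrange(.data$geomean, .data$rank_deltact, .data$gene_id) |>
    dplyr::mutate(final_rank = dplyr::row_number())
}

extract_ranks <- function(x) {
  tbl <- if (is.data.frame(x)) x else x$ranking
  if (!all(c("gene_id", "rank") %in% names(tbl))) {
    abort("each method result needs gene_id and rank")
  }
  dplyr::select(tbl, "gene_id", "rank")
}
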