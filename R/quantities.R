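#' Convert Ct values to relative quantities
#'
#' Standard preprocessing for geNorm-style analyses: each gene is calibrated
#' to its own lowest Ct (highest abundance) and quantities follow
#' Q = E^(minCt - Ct), so per gene max(Q) = 1. E is the amplification
#' efficiency per cycle; 2 means perfect doubling.
#'
#' Genes with any missing Ct are dropped with a warning (complete-case per
#' gene) so every retained gene is observed on the full common sample set.
#'
#' @param ct Wide Ct tibble (`gene_id` + sample columns).
#' @param efficiency Amplification efficiency, default 2.
#' @return Wide tibble of relative quantities, attribute `"efficiency"` set.
#' @export
ct_to_quantity <- function(ct, efficiency = 2) {
  stopifnot(efficiency > 1)
  m <- ct_matrix(ct, drop_incomplete = TRUE)
  q <- efficiency^(apply(m, 1, min) - m)
  dimnames(q) <- dimnames(m)
  out <- matrix_to_wide(q)
  attr(out, "efficiency") <- efficiency
  out
}

# wide Ct tibble -> matrix; complete-case per gene with a warning
ct_matrix <- function(ct, drop_incomplete = TRUE) {
  assert_wide_table(ct, "Ct table", allow_na = TRUE)
  m <- wide_to_matrix(ct)
  if (drop_incomplete && anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    warn(sprintf("dropping %d gene(s) with missing Ct: %s",
                 length(bad), paste(bad, collapse = ", ")))
    m <- m[!rownames(m) %in% bad, , drop = FALSE]
  }
  m
}
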