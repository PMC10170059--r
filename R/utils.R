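# internal helpers shared across modules

# geometric mean; x must be > 0
geomean <- function(x) exp(mean(log(x)))

# average ranks, ascending (ties share the mean of their positions)
rank_avg <- function(x) rank(x, ties.method = "average")

# gene x sample numeric matrix from a wide tibble whose first column is gene_id
wide_to_matrix <- function(tbl, id_col = "gene_id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[id_col]]
  m
}

matrix_to_wide <- function(m, id_col = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(out, !!id_col := rownames(m), .before = 1)
}

assert_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  }
  invisible(x)
}

# check a wide gene-by-sample tibble: first col gene_id, rest numeric
assert_wide_table <- function(tbl, what = "table", allow_na = FALSE,
                              min_value = -Inf) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2 || names(tbl)[1] != "gene_id") {
    abort(sprintf("%s must be a data frame with a first column 'gene_id'", what))
  }
  assert_unique(tbl$gene_id, "gene ids")
  assert_unique(names(tbl)[-1], "sample ids")
  vals <- as.matrix(tbl[-1])
  if (!is.numeric(vals)) abort(sprintf("%s has non-numeric value columns", what))
  bad <- which(!is.finite(vals) & !(allow_na & is.na(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("%s: non-finite value at gene '%s', sample '%s'",
                  what, tbl$gene_id[bad[1, 1]], names(tbl)[-1][bad[1, 2]]))
  }
  low <- which(vals < min_value, arr.ind = TRUE)
  if (nrow(low) > 0) {
    abort(sprintf("%s: value %g below %g at gene '%s', sample '%s'",
                  what, vals[low[1, , drop = FALSE]], min_value,
                  tbl$gene_id[low[1, 1]], names(tbl)[-1][low[1, 2]]))
  }
  invisible(tbl)
}
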