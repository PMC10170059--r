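#' Average biological replicates within each condition
#'
#' Replicates are averaged on the TPM scale (arithmetic mean) before any
#' log transform, so the condition — not the replicate — becomes the unit
#' of variation for the downstream coefficient-of-variation screen.
#'
#' @param expr Wide expression tibble from [read_expression()] or
#'   [simulate_expression()] (needs a `"sample_sheet"` attribute), or any
#'   wide tibble plus an explicit `sample_sheet`.
#' @param sample_sheet Optional sample sheet tibble overriding the attribute.
#' @return A wide tibble with one column per condition, column order
#'   following first appearance in the sample sheet.
#' @export
collapse_replicates <- function(expr, sample_sheet = NULL) {
  sheet <- sample_sheet %||% attr(expr, "sample_sheet")
  if (is.null(sheet)) abort("no sample sheet available; pass `sample_sheet`")
  assert_wide_table(expr, "expression table", min_value = 0)
  m <- wide_to_matrix(expr)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$condition)) abort("sample sheet does not cover all samples")
  conds <- unique(sheet$condition)
  collapsed <- vapply(conds, function(cc) {
    rowMeans(m[, sheet$condition == cc, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1) collapsed <- matrix(collapsed, nrow = 1)
  dimnames(collapsed) <- list(rownames(m), conds)
  matrix_to_wide(collapsed)
}

#' Per-gene log2(TPM) summary statistics
#'
#' Computes, for each gene, the mean and sample standard deviation of
#' log2(TPM) across columns and the coefficient of variation
#' CV = SD / mean. Genes with any non-positive TPM cannot be log-transformed
#' and are flagged `nonpositive_tpm` with `NA` statistics: a reference gene
#' must be detectably expressed in every condition, and a pseudocount would
#' distort CV exactly where the cut-offs bite.
#'
#' @param expr Wide tibble of TPM, typically already collapsed to one column
#'   per condition by [collapse_replicates()]. Needs at least 2 value
#'   columns (CV is undefined otherwise).
#' @return Tibble with columns `gene_id`, `n_conditions`, `mean_log2tpm`,
#'   `sd_log2tpm`, `cv`, `excluded_reason` (`"none"` or `"nonpositive_tpm"`
#'   at this stage).
#' @export
gene_log_stats <- function(expr) {
  assert_wide_table(expr, "expression table", min_value = 0)
  m <- wide_to_matrix(expr)
  if (ncol(m) < 2) abort("need at least 2 columns to compute CV")
  nonpos <- unname(apply(m, 1, function(x) any(x <= 0)))
  lg <- log2(m)
  mu <- unname(rowMeans(lg))
  sdv <- unname(apply(lg, 1, sd))
  tibble::tibble(
    gene_id = rownames(m),
    n_conditions = ncol(m),
    mean_log2tpm = ifelse(nonpos, NA_real_, mu),
    sd_log2tpm = ifelse(nonpos, NA_real_, sdv),
    cv = ifelse(nonpos, NA_real_, sdv / mu),
    excluded_reason = ifelse(nonpos, "nonpositive_tpm", "none")
  )
}

#' Screen for candidate reference genes by expression level and variability
#'
#' A gene passes when mean log2(TPM) exceeds `min_mean` (low-expression
#' genes are hard to quantify by RT-qPCR), its SD of log2(TPM) is below
#' `max_sd`, and its CV is below `max_cv`. All three comparisons are strict;
#' genes sitting exactly on a cut-off are excluded. `excluded_reason`
#' records the first failing filter in the order low_expression, high_sd,
#' high_cv (after the upstream nonpositive_tpm flag).
#'
#' @param stats Per-gene statistics from [gene_log_stats()], or a wide TPM
#'   tibble (in which case [gene_log_stats()] is applied first).
#' @param min_mean Minimum mean log2(TPM), default 5.
#' @param max_sd Maximum SD of log2(TPM), default 1.
#' @param max_cv Maximum CV, default 0.2.
#' @return An object of class `ref_screen`: list with `stats` (the input
#'   tibble plus final `excluded_reason` and `candidate` flag), `candidates`
#'   (passing genes sorted by ascending CV, ties by gene id), `n_total`,
#'   `n_candidates`, `fraction_candidates` (percent), and the thresholds.
#' @export
screen_candidates <- function(stats, min_mean = 5, max_sd = 1, max_cv = 0.2) {
  if (any(c(min_mean, max_sd, max_cv) <= 0)) abort("thresholds must be > 0")
  if (!all(c("mean_log2tpm", "sd_log2tpm", "cv") %in% names(stats))) {
    stats <- gene_log_stats(stats)
  }
  if (nrow(stats) == 0) abort("empty statistics table")
  stats <- dplyr::mutate(stats, excluded_reason = dplyr::case_when(
    .data$excluded_reason != "none" ~ .data$excluded_reason,
    !(.data$mean_log2tpm > min_mean) ~ "low_expression",
    !(.data$sd_log2tpm < max_sd) ~ "high_sd",
    !(.data$cv < max_cv) ~ "high_cv",
    TRUE ~ "none"
  ))
  stats <- dplyr::mutate(stats, candidate = .data$excluded_reason == "none")
  candidates <- stats |>
    dplyr::filter(.data$candidate) |>
    dplyr::arrange(.data$cv, .data$gene_id) |>
    dplyr::select(-"candidate")
  res <- list(
    stats = stats,
    candidates = candidates,
    n_total = nrow(stats),
    n_candidates = nrow(candidates),
    fraction_candidates = 100 * nrow(candidates) / nrow(stats),
    thresholds = c(min_mean = min_mean, max_sd = max_sd, max_cv = max_cv)
  )
  structure(res, class = "ref_screen")
}

#' Candidate fraction as the conventional summary line
#'
#' Formats "n (pct%) of total" with the percentage rounded to 2 decimals,
#' e.g. `6834 (15.82%) of 43209`.
#'
#' @param n_candidates,n_total Counts, or a `ref_screen` object as first
#'   argument.
#' @return Character scalar.
#' @export
screen_summary_line <- function(n_candidates, n_total = NULL) {
  if (inherits(n_candidates, "ref_screen")) {
    n_total <- n_candidates$n_total
    n_candidates <- n_candidates$n_candidates
  }
  sprintf("%d (%.2f%%) of %d", n_candidates,
          round(100 * n_candidates / n_total, 2), n_total)
}

#' Top candidate reference genes by ascending CV
#'
#' @param screen A `ref_screen` object.
#' @param n Number of genes to return (default 10). If fewer candidates
#'   exist, all are returned with a warning.
#' @return Tibble of the `n` most stable candidates with their statistics.
#' @export
top_candidates <- function(screen, n = 10) {
  stopifnot(inherits(screen, "ref_screen"), n >= 1)
  if (n > screen$n_candidates) {
    warn(sprintf("only %d candidates available (requested %d)",
                 screen$n_candidates, n))
    n <- screen$n_candidates
  }
  head(screen$candidates, n)
}

#' Venn-partition counts of candidate sets across datasets
#'
#' Compares the candidate reference-gene sets screened from two or three
#' datasets by exact gene-id membership. Reports, for every non-empty
#' combination of datasets, the number of genes in exactly that combination
#' (`n_exclusive`, the Venn region) and in the full intersection of the
#' combination (`n_total`).
#'
#' @param sets Named list (2 or 3 elements) of `ref_screen` objects or
#'   character vectors of gene ids.
#' @return Tibble with columns `datasets` (e.g. `"early&adult"`), `degree`,
#'   `n_exclusive`, `n_total`.
#' @export
intersect_candidates <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    abort("`sets` must be a named list of 2 or 3 candidate sets")
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    abort("each candidate set needs a distinct label")
  }
  ids <- lapply(sets, function(s) {
    if (inherits(s, "ref_screen")) s$candidates$gene_id else as.character(s)
  })
  labels <- names(ids)
  universe <- unique(unlist(ids))
  member <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  combos <- purrr::map(seq_along(labels), ~ utils::combn(labels, .x, simplify = FALSE)) |>
    purrr::flatten()
  purrr::map_dfr(combos, function(cmb) {
    inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb)
    exact <- inside & rowSums(member[, setdiff(labels, cmb), drop = FALSE]) == 0
    tibble::tibble(datasets = paste(cmb, collapse = "&"),
                   degree = length(cmb),
                   n_exclusive = sum(exact),
                   n_total = sum(inside))
  })
}

#' @export
print.ref_screen <- function(x, ...) {
  cat("Candidate reference-gene screen\n")
  cat(sprintf("  thresholds: mean log2(TPM) > %g, SD < %g, CV < %g\n",
              x$thresholds["min_mean"], x$thresholds["max_sd"],
              x$thresholds["max_cv"]))
  cat(" ", screen_summary_line(x), "candidate reference genes\n")
  invisible(x)
}

#' @rdname screen_candidates
#' @param x A `ref_screen` object.
#' @param ... Unused.
#' @export
tidy.ref_screen <- function(x, ...) x$stats

#' @rdname screen_candidates
#' @export
glance.ref_screen <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_candidates = x$n_candidates,
                 fraction_candidates = x$fraction_candidates)
}
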