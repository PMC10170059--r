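#' NormFinder model-based stability analysis
#'
#' Works on the log2 scale of relative quantities (equivalently, on negated
#' Ct up to a per-gene constant). The model decomposes log expression into
#' gene, sample and — when sample groups are supplied — gene-by-group
#' effects plus residual noise with a gene-specific variance. A candidate
#' reference gene is stable when its residual (intragroup) variance is small
#' and, in grouped mode, when its systematic deviation between groups is
#' small too.
#'
#' Ungrouped mode estimates the per-gene residual standard deviation from
#' the two-way (gene + sample) residuals, with a bias correction for the
#' panel size: with G genes the raw residual mean square of gene g has
#' expectation sigma_g^2 (G-2)/G + mean(sigma^2)/G, so
#' sigma_g^2 is estimated by G/(G-2) * (s_g^2 - mean(s^2)/(G-1)), floored
#' at zero. Stability is sigma_g (lower = more stable).
#'
#' Grouped mode additionally estimates, per gene and group, the intergroup
#' deviation d (the gene's group mean relative to its grand mean, on
#' sample-centred data), shrinks it towards zero by the empirical-Bayes
#' factor gamma^2 / (gamma^2 + sigma_g^2/n_group) — gamma^2 being the
#' method-of-moments estimate of the variance of true intergroup deviations
#' across genes — and reports the stability value as the mean over groups of
#' |d_shrunk| + sigma_g/sqrt(n_group). Both variance sources therefore
#' penalise a gene: systematic group differences (shrunken so that noisy
#' deviation estimates are discounted) and sample-to-sample noise.
#'
#' @param ct Wide Ct tibble (`gene_id` + sample columns); genes with missing
#'   Ct are dropped with a warning.
#' @param groups Optional sample grouping: a named character vector
#'   (sample id -> group), a sample-sheet tibble with a `group` column, or
#'   `NULL` to use the `group` column of the table's attached sample sheet
#'   if there is one. Each group needs at least 2 samples.
#' @param efficiency Amplification efficiency used for the log conversion,
#'   default 2 (so one Ct unit = one log2 unit).
#' @return An object of class `ref_normfinder`: list with `ranking` (tibble
#'   `gene_id`, `stability`, `intragroup_sd`, `rank`), `mode`
#'   (`"grouped"`/`"ungrouped"`), and in grouped mode `group_deviation`
#'   (tibble `gene_id`, `group`, `d`, `d_shrunk`).
#' @export
normfinder <- function(ct, groups = NULL, efficiency = 2) {
  m <- ct_matrix(ct)
  groups <- resolve_groups(ct, groups, colnames(m))
  # log2-scale expression: higher = more template
  y <- -m * log2(efficiency)

  if (is.null(groups)) {
    if (nrow(y) < 3) abort("ungrouped NormFinder needs at least 3 genes")
    if (ncol(y) < 3) abort("ungrouped NormFinder needs at least 3 samples")
    sig <- nf_intragroup_sd(y)
    ranking <- tibble::tibble(gene_id = rownames(y),
                              stability = sig, intragroup_sd = sig)
    dev_tbl <- NULL
    mode <- "ungrouped"
  } else {
    tab <- table(groups)
    if (length(tab) < 2) abort("grouped NormFinder needs at least 2 groups")
    if (any(tab < 2)) {
      abort(sprintf("group(s) with fewer than 2 samples: %s",
                    paste(names(tab)[tab < 2], collapse = ", ")))
    }
    if (nrow(y) < 3) abort("grouped NormFinder needs at least 3 genes")
    grp_names <- names(tab)
    ng <- as.integer(tab)
    g <- nrow(y)

    # gene-specific residual variance, estimated within each group then
    # pooled across groups (weights n_k - 1)
    sig2_by_grp <- vapply(grp_names, function(k) {
      nf_intragroup_sd(y[, groups == k, drop = FALSE])^2
    }, numeric(g))
    if (g == 1) sig2_by_grp <- matrix(sig2_by_grp, nrow = 1)
    w <- (ng - 1) / sum(ng - 1)
    sig2 <- as.vector(sig2_by_grp %*% w)

    # intergroup deviation on sample-centred data: removes sample effects,
    # then contrasts each gene's group mean with its grand mean
    z <- sweep(y, 2, colMeans(y))
    grp_mean <- vapply(grp_names, function(k) {
      rowMeans(z[, groups == k, drop = FALSE])
    }, numeric(g))
    if (g == 1) grp_mean <- matrix(grp_mean, nrow = 1)
    d <- grp_mean - rowMeans(z) # genes x groups

    # method-of-moments variance of true intergroup deviations: observed
    # spread of d minus its sampling variance sigma^2/n
    samp_var <- sweep(matrix(sig2, g, length(ng)), 2, ng, `/`)
    k <- length(ng)
    gamma2 <- max(0, sum(d^2) / (g * (k - 1)) - mean(samp_var))

    denom <- gamma2 + samp_var
    shrink <- ifelse(denom > 0, gamma2 / denom, 0) # 0/0 guard: nothing to shrink
    d_shrunk <- d * shrink
    rho <- rowMeans(abs(d_shrunk) + sqrt(samp_var))

    ranking <- tibble::tibble(gene_id = rownames(y),
                              stability = rho, intragroup_sd = sqrt(sig2))
    dev_tbl <- tibble::tibble(
      gene_id = rep(rownames(y), times = k),
      group = rep(grp_names, each = g),
      d = as.vector(d),
      d_shrunk = as.vector(d_shrunk)
    )
    mode <- "grouped"
  }

  ranking <- ranking |>
    dplyr::mutate(rank = rank_avg(.data$stability)) |>
    dplyr::arrange(.data$rank, .data$gene_id)
  structure(list(ranking = ranking, mode = mode, group_deviation = dev_tbl),
            class = "ref_normfinder")
}

# bias-corrected per-gene residual SD from two-way (gene + sample) residuals
nf_intragroup_sd <- function(y) {
  g <- nrow(y)
  n <- ncol(y)
  if (g < 3 || n < 2) abort("need >= 3 genes and >= 2 samples per group")
  r <- y - rowMeans(y) - matrix(colMeans(y), g, n, byrow = TRUE) + mean(y)
  s2 <- rowSums(r^2) / (n - 1)
  sig2 <- pmax(0, g / (g - 2) * (s2 - mean(s2) / (g - 1)))
  setNames(sqrt(sig2), rownames(y))
}

resolve_groups <- function(ct, groups, samples) {
  if (is.null(groups)) {
    sheet <- attr(ct, "sample_sheet")
    if (!is.null(sheet) && "group" %in% names(sheet) && !anyNA(sheet$group)) {
      groups <- setNames(as.character(sheet$group), sheet$sample_id)
    } else {
      return(NULL)
    }
  } else if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("grouping table needs columns sample_id and group")
    }
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  miss <- setdiff(samples, names(groups))
  if (length(miss) > 0) {
    abort(sprintf("no group for sample(s): %s", paste(miss, collapse = ", ")))
  }
  unname(groups[samples])
}

#' @export
print.ref_normfinder <- function(x, ...) {
  cat(sprintf("NormFinder stability ranking (%s mode; low = stable)\n", x$mode))
  print(x$ranking, n = Inf)
  invisible(x)
}

#' @rdname normfinder
#' @param x A `ref_normfinder` object.
#' @param ... Unused.
#' @export
tidy.ref_normfinder <- function(x, ...) x$ranking
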