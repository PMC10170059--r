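#' Specification of a synthetic reference-gene study
#'
#' Describes a gene-by-sample TPM matrix with two gene classes on the log2
#' scale: a stable minority whose per-condition values vary with a small SD
#' (so the mean-expression, SD and CV screening filters all pass by
#' construction) and an unstable majority whose SD across conditions is
#' large (condition-dependent expression shifts). Replicates within a
#' condition add independent log-scale noise. Ct values are generated from
#' the global linear calibration Ct = ct_intercept + ct_slope * log2(TPM)
#' plus Gaussian noise.
#'
#' Defaults describe a developmental-series-scale design: 2000 genes over
#' 12 conditions with 3 biological replicates, 10% stable genes, stable
#' per-condition SD in 0.01-0.15 log2 units (comfortably inside the SD < 1
#' and CV < 0.2 cut-offs for means above 5), unstable SD in 1.2-3.0, mean
#' log2(TPM) uniform in 6-18, replicate noise SD 0.1, and the calibration
#' coefficients -0.5405 / 34.51 with Ct noise SD 2.5 (a weak-correlation
#' regime reflecting that a single global line explains little of the
#' gene-to-gene Ct variation).
#'
#' @param n_genes,n_conditions,n_replicates Design size.
#' @param fraction_stable Fraction of genes in the stable class.
#' @param stable_sd_range,unstable_sd_range Per-condition log2 SD ranges.
#' @param mean_log2tpm_range Range of per-gene mean log2(TPM).
#' @param replicate_noise_sd Log2 SD of replicate noise within a condition.
#' @param ct_slope,ct_intercept,ct_noise_sd Ct generative model.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `ref_synthspec`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_conditions = 12, n_replicates = 3,
                           fraction_stable = 0.1,
                           stable_sd_range = c(0.01, 0.15),
                           unstable_sd_range = c(1.2, 3.0),
                           mean_log2tpm_range = c(6, 18),
                           replicate_noise_sd = 0.1,
                           ct_slope = -0.5405, ct_intercept = 34.51,
                           ct_noise_sd = 2.5, seed = 1L) {
  stopifnot(n_genes >= 1, n_conditions >= 2, n_replicates >= 1,
            fraction_stable >= 0, fraction_stable <= 1,
            all(stable_sd_range >= 0), all(unstable_sd_range >= 0),
            replicate_noise_sd >= 0, ct_noise_sd >= 0)
  structure(as.list(environment()), class = "ref_synthspec")
}

#' Simulate a TPM expression matrix with known truth labels
#'
#' Per gene: the mean log2(TPM) is uniform on `mean_log2tpm_range`; stable
#' genes draw one per-condition log2 value from Normal(mean, sd) with sd
#' uniform on `stable_sd_range`, unstable genes likewise on
#' `unstable_sd_range`; each replicate adds Normal(0, replicate_noise_sd);
#' TPM = 2^value. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A wide expression tibble (sample sheet attached as attribute
#'   `"sample_sheet"`) with attribute `"truth"`: a tibble `gene_id`,
#'   `status` (`"stable"`/`"unstable"`), `true_mean`, `true_sd`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "ref_synthspec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  n_stable <- round(g * spec$fraction_stable)
  status <- rep(c("stable", "unstable"), c(n_stable, g - n_stable))
  gene_ids <- sprintf("gene_%05d", seq_len(g))
  mu <- runif(g, spec$mean_log2tpm_range[1], spec$mean_log2tpm_range[2])
  sd_rng <- rbind(spec$stable_sd_range, spec$unstable_sd_range)
  true_sd <- runif(g, sd_rng[(status == "unstable") + 1, 1],
                   sd_rng[(status == "unstable") + 1, 2])

  cond_ids <- sprintf("cond_%02d", seq_len(spec$n_conditions))
  cond_vals <- matrix(rnorm(g * spec$n_conditions, mean = mu, sd = true_sd),
                      nrow = g) # recycles mu, true_sd down columns
  sheet <- tidyr::expand_grid(condition = cond_ids,
                              replicate = seq_len(spec$n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_rep%d", .data$condition, .data$replicate)) |>
    dplyr::select("sample_id", "condition", "replicate")
  rep_noise <- matrix(rnorm(g * nrow(sheet), sd = spec$replicate_noise_sd),
                      nrow = g)
  log2_vals <- cond_vals[, match(sheet$condition, cond_ids), drop = FALSE] + rep_noise
  tpm <- 2^log2_vals
  dimnames(tpm) <- list(gene_ids, sheet$sample_id)

  out <- attach_sample_sheet(matrix_to_wide(tpm), sheet)
  attr(out, "truth") <- tibble::tibble(gene_id = gene_ids, status = status,
                                       true_mean = mu, true_sd = true_sd)
  out
}

#' Simulate a Ct table for a gene panel from an expression matrix
#'
#' Ct[g, s] = ct_intercept + ct_slope * log2(TPM[g, s]) + Normal(0, sd),
#' where sd is `spec$ct_noise_sd` or a per-gene override. When `groups` is
#' given, a gene-by-group shift Normal(0, group_shift_sd) is added, giving
#' grouped designs a systematic intergroup component for model-based
#' stability analyses.
#'
#' @param expr Wide expression tibble (TPM > 0).
#' @param spec A [synthetic_spec()] providing the Ct model.
#' @param panel Gene ids to include (default: all genes in `expr`).
#' @param gene_noise_sd Optional named vector (gene id -> Ct noise SD)
#'   overriding `spec$ct_noise_sd` per gene, e.g. to inject high-noise
#'   genes into a panel.
#' @param groups Optional named vector (sample id -> group label).
#' @param group_shift_sd SD of the per-gene, per-group Ct shift (default 0).
#' @param seed Seed for the Ct noise; defaults to `spec$seed + 1` so
#'   expression and Ct noise are independent streams of one master seed.
#' @return Wide Ct tibble; sample sheet (with `group` when given) attached.
#' @export
simulate_ct <- function(expr, spec, panel = NULL, gene_noise_sd = NULL,
                        groups = NULL, group_shift_sd = 0,
                        seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "ref_synthspec"))
  m <- wide_to_matrix(expr)
  panel <- panel %||% rownames(m)
  miss <- setdiff(panel, rownames(m))
  if (length(miss) > 0) {
    abort(sprintf("panel gene(s) not in expression matrix: %s",
                  paste(miss, collapse = ", ")))
  }
  m <- m[panel, , drop = FALSE]
  if (any(m <= 0)) abort("TPM must be > 0 to simulate Ct")
  set.seed(seed)
  noise_sd <- rep(spec$ct_noise_sd, length(panel))
  if (!is.null(gene_noise_sd)) {
    idx <- match(names(gene_noise_sd), panel)
    noise_sd[idx[!is.na(idx)]] <- gene_noise_sd[!is.na(idx)]
  }
  ct <- spec$ct_intercept + spec$ct_slope * log2(m) +
    matrix(rnorm(length(m), sd = noise_sd), nrow = nrow(m)) # recycled by gene
  if (!is.null(groups)) {
    grp <- unname(groups[colnames(m)])
    if (anyNA(grp)) abort("`groups` must cover every sample")
    for (lev in unique(grp)) {
      ct[, grp == lev] <- ct[, grp == lev] +
        rnorm(nrow(ct), sd = group_shift_sd)
    }
  }
  dimnames(ct) <- dimnames(m)
  out <- matrix_to_wide(ct)
  sheet <- attr(expr, "sample_sheet")
  if (!is.null(sheet)) {
    if (!is.null(groups)) sheet$group <- unname(groups[sheet$sample_id])
    out <- attach_sample_sheet(out, sheet)
  }
  out
}
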