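# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (explicit loops, textbook formulas) and
# never call the implementation they check.

make_wide <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                      samples = sprintf("s%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  tibble::add_column(tibble::as_tibble(m, .name_repair = "minimal"),
                     gene_id = genes, .before = 1)
}

wide_mat <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl$gene_id
  m
}

make_sheet <- function(samples, conditions, replicates = NULL, group = NULL) {
  sheet <- tibble::tibble(sample_id = samples, condition = conditions,
                          replicate = replicates %||%
                            stats::ave(seq_along(samples), conditions, FUN = seq_along))
  if (!is.null(group)) sheet$group <- group
  sheet
}

random_ct_tbl <- function(g, n, seed) {
  set.seed(seed)
  make_wide(matrix(runif(g * n, 18, 32), g, n))
}

# mean/SD/CV of log2 values per row, textbook formulas
oracle_cv <- function(tpm_row) {
  x <- log2(tpm_row)
  mu <- sum(x) / length(x)
  sdv <- sqrt(sum((x - mu)^2) / (length(x) - 1))
  c(mean = mu, sd = sdv, cv = sdv / mu)
}

# geNorm M by explicit double loop over gene pairs
oracle_genorm_m <- function(q) {
  lg <- log2(q)
  g <- nrow(lg)
  out <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k != j) sds <- c(sds, stats::sd(lg[j, ] - lg[k, ]))
    }
    out[j] <- mean(sds)
  }
  setNames(out, rownames(q))
}

# geNorm V for a given stability order (most stable first)
oracle_genorm_v <- function(q, order_ids) {
  lg <- log2(q[order_ids, , drop = FALSE])
  g <- nrow(lg)
  vapply(2:(g - 1), function(n) {
    nf_n <- apply(lg[1:n, , drop = FALSE], 2, mean)
    nf_n1 <- apply(lg[1:(n + 1), , drop = FALSE], 2, mean)
    stats::sd(nf_n - nf_n1)
  }, numeric(1))
}

# delta-Ct mean pairwise SD by explicit double loop
oracle_delta_ct <- function(ct) {
  g <- nrow(ct)
  out <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k != j) sds <- c(sds, stats::sd(ct[j, ] - ct[k, ]))
    }
    out[j] <- mean(sds)
  }
  setNames(out, rownames(ct))
}

# BestKeeper descriptive statistics and index correlation, direct formulas
oracle_bestkeeper <- function(ct) {
  n <- ncol(ct)
  index <- apply(ct, 2, function(x) exp(mean(log(x))))
  list(
    index = index,
    sd = apply(ct, 1, stats::sd),
    cv_pct = 100 * apply(ct, 1, stats::sd) / rowMeans(ct),
    geo_mean = apply(ct, 1, function(x) exp(mean(log(x)))),
    r = apply(ct, 1, function(x) stats::cor(x, index)),
    p = apply(ct, 1, function(x) stats::cor.test(x, index)$p.value)
  )
}

# OLS slope/intercept/R^2/p via normal equations, no lm
oracle_ols <- function(x, y) {
  n <- length(x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  yhat <- b0 + b1 * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  fstat <- (ss_tot - ss_res) / (ss_res / (n - 2))
  list(slope = b1, intercept = b0, r_squared = r2,
       p = stats::pf(fstat, 1, n - 2, lower.tail = FALSE))
}
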