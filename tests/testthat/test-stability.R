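# -- Ct -> relative quantity ------------------------------------------------

test_that("Ct to quantity calibrates each gene to its lowest Ct", {
  ct <- make_wide(matrix(c(20, 21, 22, 25, 25, 25), 2, 3, byrow = TRUE))
  q <- ct_to_quantity(ct, efficiency = 2)
  expect_equal(unname(wide_mat(q)[1, ]), c(1, 0.5, 0.25))
  expect_equal(unname(wide_mat(q)[2, ]), c(1, 1, 1))
  # arbitrary efficiency matches direct exponentiation, per-gene max is 1
  set.seed(3)
  ct2 <- random_ct_tbl(5, 6, seed = 3)
  q2 <- wide_mat(ct_to_quantity(ct2, efficiency = 1.9))
  m <- wide_mat(ct2)
  expect_equal(q2, 1.9^(apply(m, 1, min) - m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(apply(q2, 1, max)), rep(1, 5))
})

test_that("genes with missing Ct are dropped complete-case with a warning", {
  ct <- random_ct_tbl(4, 5, seed = 8)
  ct[2, 3] <- NA
  expect_warning(q <- ct_to_quantity(ct), "g02")
  expect_identical(q$gene_id, c("g01", "g03", "g04"))
})

# -- geNorm ------------------------------------------------------------------

test_that("proportional quantity rows give M = 0 and V = 0", {
  base <- c(1, 0.5, 0.25, 0.125)
  q <- make_wide(rbind(base, 2 * base, 0.5 * base) / 2,
                 genes = c("j", "k", "l"))
  res <- genorm(q)
  expect_equal(res$ranking$m_value, rep(0, 3))
  expect_equal(res$pairwise_variation$v, 0)
})

test_that("a noisy gene among proportional rows is excluded first", {
  set.seed(14)
  base <- runif(6, 0.1, 1)
  q <- make_wide(rbind(base, 2 * base, 0.7 * base,
                       base * 2^rnorm(6, sd = 1.5)),
                 genes = c("a", "b", "c", "noisy"))
  res <- genorm(q)
  expect_identical(res$exclusion_order[1], "noisy")
  expect_equal(res$ranking$rank[res$ranking$gene_id == "noisy"], 4)
  # first-round M agrees with the double-loop oracle
  expect_equal(setNames(res$m_first_round$m_value, res$m_first_round$gene_id),
               oracle_genorm_m(wide_mat(q))[res$m_first_round$gene_id],
               tolerance = 1e-10)
})

test_that("geNorm M and V match the brute-force oracle on random panels", {
  for (seed in 1:25) {
    set.seed(seed)
    g <- sample(3:10, 1)
    n <- sample(3:10, 1)
    q <- make_wide(matrix(2^rnorm(g * n, sd = 1), g, n))
    q[-1] <- sweep(q[-1], 1, apply(q[-1], 1, max), `/`)
    res <- genorm(q)
    om <- oracle_genorm_m(wide_mat(q))
    expect_equal(setNames(res$m_first_round$m_value, res$m_first_round$gene_id),
                 om[res$m_first_round$gene_id], tolerance = 1e-10)
    expect_equal(res$pairwise_variation$v,
                 oracle_genorm_v(wide_mat(q), res$ranking$gene_id),
                 tolerance = 1e-10)
  }
})

test_that("geNorm needs 3 genes and positive quantities", {
  q <- make_wide(matrix(c(1, 0.5, 1, 0.25), 2, 2))
  expect_error(genorm(q), "at least 3 genes")
  q3 <- make_wide(matrix(c(1, 0.5, 1, 0.25, 0, 1), 3, 2))
  expect_error(genorm(q3), "> 0")
})

# -- NormFinder --------------------------------------------------------------

test_that("a gene with constant sample-centred values is the most stable", {
  set.seed(21)
  m <- matrix(rnorm(5 * 6, mean = 25, sd = 1.5), 5, 6)
  shift <- rnorm(6, sd = 2)
  m <- sweep(m, 2, shift, `+`)
  m[3, ] <- 24 + shift # tracks the sample effects exactly
  res <- normfinder(make_wide(m))
  expect_identical(res$ranking$gene_id[res$ranking$rank == min(res$ranking$rank)][1],
                   "g03")
})

test_that("grouped mode gives near-zero stability to a no-signal gene", {
  set.seed(22)
  groups <- setNames(rep(c("ctl", "trt"), each = 6), sprintf("s%02d", 1:12))
  # genes 1/3 carry opposite group deviations (sum-to-zero, as the model is
  # identified); gene 2 has equal group means and residuals ~ 0
  m <- matrix(rnorm(4 * 12, mean = 26, sd = 0.6), 4, 12)
  m[1, ] <- m[1, ] + rep(c(1.5, -1.5), each = 6)
  m[3, ] <- m[3, ] + rep(c(-1.5, 1.5), each = 6)
  m[2, ] <- 25 + rnorm(12, sd = 1e-4)
  res <- normfinder(make_wide(m), groups = groups)
  row <- res$ranking[res$ranking$gene_id == "g02", ]
  dev <- res$group_deviation[res$group_deviation$gene_id == "g02", ]
  expect_lt(max(abs(dev$d_shrunk)), 0.3)
  expect_lt(row$stability, 0.3)
  expect_identical(res$ranking$gene_id[1], "g02")
  expect_true(all(res$ranking$stability >= 0))
})

test_that("grouped stability recovers the noise ordering of a known model", {
  # 8 genes whose true residual SDs span 0.1..0.7, plus sample effects and
  # modest sum-to-zero intergroup deviations (SD 0.05 per group). Stability
  # estimates should rank genes like their true residual SDs.
  set.seed(25)
  sds <- sqrt(seq(0.01, 0.5, length.out = 8))
  groups <- setNames(rep(c("g1", "g2"), each = 10), sprintf("s%02d", 1:20))
  rho <- replicate(100, {
    delta <- rnorm(8, sd = 0.05)
    delta <- delta - mean(delta)
    m <- matrix(rnorm(8 * 20, mean = 25, sd = sds), 8, 20) +
      matrix(rnorm(20, sd = 0.5), 8, 20, byrow = TRUE) + # sample effects
      cbind(delta, -delta)[, rep(1:2, each = 10)]
    res <- normfinder(make_wide(m), groups = groups)
    cor(res$ranking$stability[match(sprintf("g%02d", 1:8),
                                    res$ranking$gene_id)],
        sds, method = "spearman")
  })
  expect_gte(mean(rho), 0.8)
})

test_that("grouped mode validates its design", {
  m <- make_wide(matrix(rnorm(12, 25), 3, 4))
  expect_error(normfinder(m, groups = setNames(c("a", "a", "a", "b"),
                                               sprintf("s%02d", 1:4))),
               "fewer than 2 samples")
  expect_error(normfinder(make_wide(matrix(rnorm(8, 25), 2, 4))),
               "at least 3 genes")
})

# -- BestKeeper --------------------------------------------------------------

test_that("identical gene rows give r = 1 and index equal to the row", {
  v <- c(20, 22, 25, 21, 23)
  ct <- make_wide(rbind(v, v, v))
  res <- bestkeeper(ct)
  expect_equal(res$index$index, v, ignore_attr = TRUE)
  expect_equal(res$ranking$r, rep(1, 3))
  expect_equal(res$ranking$p_value, rep(0, 3))
})

test_that("a constant Ct row takes the top BestKeeper rank with NA r", {
  set.seed(33)
  m <- rbind(rep(24, 6), matrix(runif(18, 20, 30), 3, 6))
  res <- bestkeeper(make_wide(m))
  top <- res$ranking[1, ]
  expect_identical(top$gene_id, "g01")
  expect_equal(top$sd_ct, 0)
  expect_true(is.na(top$r))
})

test_that("BestKeeper statistics match the direct-formula oracle", {
  for (seed in 1:25) {
    ct <- random_ct_tbl(sample(2:10, 1), sample(3:10, 1), seed = 100 + seed)
    m <- wide_mat(ct)
    res <- bestkeeper(ct)
    o <- oracle_bestkeeper(m)
    idx <- match(res$ranking$gene_id, rownames(m))
    expect_equal(res$index$index, o$index, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$ranking$sd_ct, o$sd[idx], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$ranking$cv_pct, o$cv_pct[idx], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$ranking$geo_mean_ct, o$geo_mean[idx], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$ranking$r, o$r[idx], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$ranking$p_value, o$p[idx], tolerance = 1e-8, ignore_attr = TRUE)
    expect_identical(res$ranking$inconsistent, unname(o$sd[idx] > 1))
  }
})

test_that("BestKeeper r is invariant to positive affine transforms of one gene", {
  ct <- random_ct_tbl(5, 8, seed = 55)
  res0 <- bestkeeper(ct)
  ct2 <- ct
  ct2[3, -1] <- ct2[3, -1] * 1.7 + 2
  res1 <- bestkeeper(ct2)
  # correlation with *its own* index is what must persist: recompute r of the
  # transformed gene against the new index via the oracle and compare
  expect_equal(res1$ranking$r[res1$ranking$gene_id == "g03"],
               oracle_bestkeeper(wide_mat(ct2))$r[["g03"]], tolerance = 1e-12)
})

# -- delta-Ct ----------------------------------------------------------------

test_that("constant Ct offsets give zero pairwise SD; two genes tie", {
  s <- c(20, 23, 26, 22)
  ct <- make_wide(rbind(s, s + 3, s - 1.5))
  res <- delta_ct(ct)
  expect_equal(res$ranking$mean_pairwise_sd, rep(0, 3))
  two <- delta_ct(random_ct_tbl(2, 6, seed = 2))
  expect_equal(two$ranking$mean_pairwise_sd[1], two$ranking$mean_pairwise_sd[2])
})

test_that("delta-Ct scores match the double-loop oracle; table symmetric", {
  for (seed in 1:25) {
    ct <- random_ct_tbl(sample(2:10, 1), sample(2:10, 1), seed = 200 + seed)
    res <- delta_ct(ct)
    o <- oracle_delta_ct(wide_mat(ct))
    expect_equal(setNames(res$ranking$mean_pairwise_sd, res$ranking$gene_id),
                 o[res$ranking$gene_id], tolerance = 1e-12)
    expect_equal(res$pairwise_sd, t(res$pairwise_sd))
    expect_equal(unname(diag(res$pairwise_sd)), rep(0, nrow(res$pairwise_sd)))
  }
})

# -- shared invariances ------------------------------------------------------

test_that("per-sample Ct shifts leave geNorm M and delta-Ct scores unchanged", {
  ct <- random_ct_tbl(6, 8, seed = 61)
  shift <- ct
  shift[-1] <- sweep(shift[-1], 2, runif(8, -3, 3), `+`)
  expect_equal(delta_ct(ct)$ranking, delta_ct(shift)$ranking, tolerance = 1e-10)
  m0 <- genorm(ct_to_quantity(ct))$m_first_round
  m1 <- genorm(ct_to_quantity(shift))$m_first_round
  expect_equal(m0, m1, tolerance = 1e-10)
})

test_that("scaling one gene's quantity row changes no geNorm M value", {
  set.seed(71)
  q <- make_wide(matrix(2^rnorm(30), 5, 6))
  q2 <- q
  q2[2, -1] <- q2[2, -1] * 37.5
  expect_equal(genorm(q)$m_first_round, genorm(q2)$m_first_round,
               tolerance = 1e-10)
})

test_that("all four methods are invariant to gene input order", {
  ct <- random_ct_tbl(7, 9, seed = 81)
  perm <- ct[sample(7), ]
  sorted <- function(tbl) dplyr::arrange(tbl, gene_id)
  expect_equal(sorted(genorm(ct_to_quantity(ct))$ranking),
               sorted(genorm(ct_to_quantity(perm))$ranking), tolerance = 1e-10)
  expect_equal(sorted(normfinder(ct)$ranking),
               sorted(normfinder(perm)$ranking), tolerance = 1e-10)
  expect_equal(sorted(bestkeeper(ct)$ranking),
               sorted(bestkeeper(perm)$ranking), tolerance = 1e-10)
  expect_equal(sorted(delta_ct(ct)$ranking),
               sorted(delta_ct(perm)$ranking), tolerance = 1e-10)
})
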