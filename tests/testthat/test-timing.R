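test_that("trajectory AUC matches geometry and a quadrature oracle", {
  B <- 50
  mids <- (seq(0, 1, length.out = B + 1)[-1] +
             seq(0, 1, length.out = B + 1)[-(B + 1)]) / 2
  const <- rep(1, B)
  step <- as.numeric(mids >= 0.5)
  ramp <- mids
  t <- toy_trajectories(rbind(const = 10 * const, step = 5 * step,
                              ramp = 2 * ramp))
  auc <- trajectory_auc(t, form = "NORM_MAX")
  expect_equal(unname(auc["const"]), 1)
  expect_equal(unname(auc["step"]), 0.5, tolerance = 0.02)
  expect_equal(unname(auc["ramp"]), 0.5, tolerance = 0.02)

  # quadrature oracle: fine-grid numeric integration of the same curve
  fine_x <- seq(min(mids), max(mids), length.out = 20000)
  fine_y <- approx(mids, ramp / max(ramp), xout = fine_x)$y
  oracle <- sum(diff(fine_x) * (head(fine_y, -1) + tail(fine_y, -1)) / 2) /
    (max(mids) - min(mids))
  expect_equal(unname(auc["ramp"]), oracle, tolerance = 1e-6)
  expect_true(all(auc >= 0 & auc <= 1))
})

test_that("onset categories split into terciles", {
  cls <- onset_category(c(a = 0.9, b = 0.5, c = 0.1))
  expect_equal(as.character(cls), c("early", "mid", "late"))

  set.seed(41)
  aucs <- setNames(runif(300), sprintf("g%03d", 1:300))
  cls2 <- onset_category(aucs)
  expect_true(all(abs(table(cls2) - 100) <= 1))

  same <- onset_category(c(a = 0.5, b = 0.5, c = 0.5))
  expect_equal(length(unique(as.character(same))), 1)
  expect_warning(two <- onset_category(c(a = 1, b = 0)), "mid")
  expect_true(all(two == "mid"))
})

test_that("enrichment scores: fold changes and rank-sum p-values", {
  # 4 vs 4 fixture; exhaustive permutation oracle for the rank-sum p
  xa <- c(1.1, 2.3, 3.1, 4.7)   # target cells, distinct values, no ties
  xb <- c(0.2, 0.9, 1.7, 2.8)
  x <- Matrix::Matrix(cbind(gA = c(xa, xb), gEq = rep(2, 8)), sparse = TRUE)
  rownames(x) <- sprintf("c%d", 1:8)
  meta <- data.frame(barcode = rownames(x),
                     cluster = rep(c("mOSN", "rest"), each = 4))
  es <- enrichment_scores(x, meta, "mOSN", n_top = 2)

  # permutation oracle: distribution of the rank-sum statistic over all
  # choose(8,4) assignments
  pool <- c(xa, xb)
  combs <- combn(8, 4)
  w_obs <- sum(rank(pool)[1:4])
  w_all <- apply(combs, 2, function(idx) sum(rank(pool)[idx]))
  mu <- mean(w_all)
  p_oracle <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(es$enrich_p[es$gene == "gA"], p_oracle, tolerance = 1e-12)

  expect_equal(es$enrich_lfc[es$gene == "gEq"], 0)
  expect_equal(es$enrich_p[es$gene == "gEq"], 1)

  # gene expressed only in the target: lfc bounded by the pseudocount rule
  x2 <- Matrix::Matrix(cbind(gOnly = c(1, 1, 1, 1, 0, 0, 0, 0),
                             gBg = rep(1, 8)), sparse = TRUE)
  rownames(x2) <- rownames(x)
  es2 <- enrichment_scores(x2, meta, "mOSN", n_top = 1)
  lfc_only <- es2$enrich_lfc[es2$gene == "gOnly"]
  expect_true(lfc_only > 20 && lfc_only <= log2((1 + 1e-9) / 1e-9))
  meta_small <- data.frame(barcode = rownames(x),
                           cluster = c("mOSN", "mOSN", rep("rest", 6)))
  expect_error(enrichment_scores(x, meta_small, "mOSN"), "fewer than 3")
})

test_that("onset/DE correlation equals the closed-form Pearson r", {
  auc <- setNames(seq(0.1, 1, length.out = 10), sprintf("g%02d", 1:10))
  de_prop <- data.frame(gene = names(auc), logfc = 2 * auc)
  expect_equal(correlate_onset_with_de(auc, de_prop)$r, 1)
  de_anti <- data.frame(gene = names(auc), logfc = -auc)
  expect_equal(correlate_onset_with_de(auc, de_anti)$r, -1)

  set.seed(42)
  lf <- rnorm(10)
  de <- data.frame(gene = names(auc), logfc = lf)
  got <- correlate_onset_with_de(auc, de)
  # direct covariance-formula oracle
  r_oracle <- sum((auc - mean(auc)) * (lf - mean(lf))) /
    sqrt(sum((auc - mean(auc))^2) * sum((lf - mean(lf))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$n, 10)
  expect_error(correlate_onset_with_de(auc[1:2],
                                       de[1:2, , drop = FALSE]), "3")
})

test_that("hypergeometric ORA matches exhaustive draw enumeration", {
  universe <- sprintf("u%02d", 1:10)
  set1 <- universe[1:4]                      # K = 4
  selected <- c(universe[1:4], universe[10]) # n = 5, k = 4
  res <- ora_test(selected, list(s1 = set1), universe)
  # enumeration oracle: all choose(10,5) draws, count those with >= 4 hits
  draws <- combn(10, 5)
  hits <- apply(draws, 2, function(idx) sum(idx <= 4))
  p_oracle <- mean(hits >= 4)
  expect_equal(res$pvalue, p_oracle, tolerance = 1e-12)
  expect_equal(res$pvalue, 6 / 252, tolerance = 1e-12)

  # k = 0 with K > 0 -> P(X >= 0) = 1; selected == universe -> p = 1
  res0 <- ora_test(universe[9:10], list(s1 = set1), universe)
  expect_equal(res0$pvalue, 1)
  resU <- ora_test(universe, list(s1 = set1), universe)
  expect_equal(resU$overlap, 4)
  expect_equal(resU$pvalue, 1)
  expect_error(ora_test("x", list(s = "x"), character(0)), "universe")
})

test_that("BH FDR matches a brute-force recomputation", {
  set.seed(43)
  p <- runif(17)^2
  sets <- setNames(as.list(sprintf("u%02d", 1:17)), sprintf("s%02d", 1:17))
  # brute force BH: p_(i) * m / i with step-up monotonization
  bh_brute <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-14)
  # and through the ORA interface
  universe <- sprintf("u%02d", 1:40)
  coll <- lapply(1:12, function(i) sample(universe, 8))
  names(coll) <- sprintf("s%02d", 1:12)
  sel <- sample(universe, 10)
  res <- ora_test(sel, coll, universe)
  expect_equal(res$fdr, bh_brute(res$pvalue), tolerance = 1e-14)
})

test_that("DE tables recompute FDR when the column is absent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = c("a", "b", "c"), logfc = c(-2, 1, 0.5),
                   pvalue = c(0.01, 0.2, 0.04))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  de <- read_de_table(f)
  expect_equal(de$fdr, p.adjust(df$pvalue, "BH"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[, 1:2], f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_de_table(f2), "pvalue")
})
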