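test_that("ssGSEA matches the brute-force running-sum oracle", {
  set.seed(41)
  for (rep in 1:5) {
    expr <- matrix(rexp(20 * 5), 20, 5,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:5)))
    sets <- list(S1 = paste0("g", sample(20, 7)),
                 S2 = paste0("g", sample(20, 5)))
    es <- ssgsea(expr, sets, min_overlap = 3)
    expect_equal(es, ssgsea_oracle(expr, sets), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("enrichment scores are rank-based and reward top expression", {
  set.seed(42)
  expr <- matrix(rexp(10), 10, 1,
                 dimnames = list(paste0("g", 1:10), "c1"))
  top3 <- rownames(expr)[order(expr[, 1], decreasing = TRUE)][1:3]
  subsets <- combn(rownames(expr), 3, simplify = FALSE)
  scores <- vapply(subsets, function(s)
    ssgsea(expr, list(S = s), min_overlap = 3)[1, 1], numeric(1))
  expect_identical(sort(subsets[[which.max(scores)]]), sort(top3))

  # invariance under strictly increasing transforms
  sets <- list(S = paste0("g", c(2, 5, 7, 9)))
  a <- ssgsea(expr, sets, min_overlap = 3)
  b <- ssgsea(expr^3 + 1, sets, min_overlap = 3)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)

  # sets below the overlap floor are skipped and recorded
  es <- ssgsea(expr, list(S = paste0("g", 1:6), none = c("x", "y", "z", "w", "v")))
  expect_identical(attr(es, "skipped"), "none")
  expect_false("none" %in% rownames(es))
})

test_that("screens use t-tests for two groups and ANOVA beyond", {
  set.seed(43)
  scores <- matrix(rnorm(30 * 40), 30, 40,
                   dimnames = list(paste0("s", 1:30), NULL))
  groups <- rep(c("pre", "post"), each = 20)
  res <- screen(scores, groups)
  ref <- apply(scores, 1L, function(y)
    t.test(y[groups == "post"], y[groups == "pre"],
           var.equal = TRUE)$p.value)
  expect_equal(res$p, unname(ref), tolerance = 1e-12)
  # ranks: permutation of 1..n with the most significant set ranked highest
  expect_setequal(res$rank, seq_len(30))
  expect_equal(res$rank[which.min(res$p)], 30)
  expect_equal(res$neg_log10_p, -log10(res$p))

  g3 <- rep(c("a", "b", "c"), length.out = 40)
  res3 <- screen(scores, g3)
  ref3 <- apply(scores, 1L, function(y)
    oneway.test(y ~ factor(g3), var.equal = TRUE)$p.value)
  expect_equal(res3$p, unname(ref3), tolerance = 1e-12)
})

test_that("identical groups give p exactly 1", {
  scores <- matrix(rnorm(5 * 12), 5, 12)
  groups <- rep(c("x", "y"), 6)
  dup <- cbind(scores[, groups == "x"], scores[, groups == "x"])
  res <- screen(dup, rep(c("x", "y"), each = 6))
  expect_true(all(res$p == 1))
})

test_that("null screens keep type-I error near nominal", {
  set.seed(44)
  pvals <- unlist(lapply(1:40, function(i) {
    scores <- matrix(rnorm(50 * 30), 50, 30)
    screen(scores, sample(rep(c("a", "b"), 15)))$p
  }))
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
  expect_lt(stats::ks.test(pvals, "punif")$statistic, 0.05)
})

test_that("expressing-cell fractions use the pooled z test", {
  expr <- rbind(gA = rep(5, 100))
  colnames(expr) <- paste0("c", 1:100)
  groups <- rep(c("pre", "post"), each = 50)
  all_on <- expressing_fraction_test(expr, "gA", groups)
  expect_equal(all_on$p, 1)

  expr2 <- rbind(g = c(rep(c(1, 0), c(80, 20)), rep(c(1, 0), c(20, 80))))
  colnames(expr2) <- paste0("c", 1:200)
  res <- expressing_fraction_test(expr2, "g",
                                  rep(c("pre", "post"), each = 100))
  cs <- suppressWarnings(prop.test(c(80, 20), c(100, 100), correct = FALSE))
  expect_equal(res$z^2, unname(cs$statistic), tolerance = 1e-9)
  expect_error(expressing_fraction_test(expr2, "missing", rep("a", 200)),
               "missing")
})

test_that("relative scores are centered on the baseline group", {
  set.seed(45)
  scores <- matrix(rnorm(4 * 20), 4, 20)
  groups <- rep(c("pre", "post"), each = 10)
  rel <- relative_scores(scores, groups, "pre")
  expect_equal(rowMeans(rel[, groups == "pre"]), rep(0, 4),
               tolerance = 1e-12)
  shifted <- relative_scores(scores + 5, groups, "pre")
  expect_equal(rel, shifted, tolerance = 1e-12)
  # a planted shift is read off the post-group mean
  scores2 <- scores
  scores2[1, groups == "post"] <- scores2[1, groups == "post"] + 0.8
  rel2 <- relative_scores(scores2, groups, "pre")
  expect_equal(mean(rel2[1, groups == "post"]) -
                 mean(rel2[1, groups == "pre"]),
               mean(scores[1, groups == "post"]) + 0.8 -
                 mean(scores[1, groups == "pre"]), tolerance = 1e-12)
  expect_error(relative_scores(scores, groups, "nope"), "empty")
})

test_that("log2 fold changes share the gene-list minimum as pseudo-count", {
  expr <- cbind(day0 = c(10, 0, 4), day60 = c(10, 8, 8))
  rownames(expr) <- c("r1", "r2", "r3")
  fc <- log2fc_from_baseline(expr, "day0", rownames(expr))
  expect_equal(fc["r1", "day60"], 0)
  pc <- 4  # minimum nonzero value over the gene list
  expect_equal(fc["r2", "day60"], log2((8 + pc) / (0 + pc)))
  expect_equal(fc["r3", "day60"], log2((8 + pc) / (4 + pc)))
  expect_true(all(is.finite(fc)))
  # doubling with a negligible pseudo-count is ~1
  expr2 <- cbind(day0 = c(1000, 0.01), day60 = c(2000, 0.01))
  rownames(expr2) <- c("big", "tiny")
  expect_equal(log2fc_from_baseline(expr2, "day0", rownames(expr2))["big", "day60"],
               1, tolerance = 0.01)
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("d0", "d1")))
  expect_error(log2fc_from_baseline(zero, "d0", c("a", "b")), "nonzero")
})
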