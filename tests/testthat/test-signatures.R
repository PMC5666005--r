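test_that("channel labels are the 96 pyrimidine-centered classes", {
  labels <- channel_labels()
  expect_length(labels, 96L)
  expect_identical(labels[1], "A[C>A]A")
  expect_identical(labels[96], "T[T>G]T")
  expect_false(anyDuplicated(labels) > 0)
})

test_that("purine-centered variants reverse-complement to the same channel", {
  a <- trinucleotide_context("C", "T", "A", "G")
  expect_identical(a$label, "A[C>T]G")
  b <- trinucleotide_context("G", "A", "C", "T")  # reverse-complement strand
  expect_identical(b$label, "A[C>T]G")
  expect_identical(a$channel, b$channel)
  expect_error(trinucleotide_context("N", "T", "A", "G"), "ACGT")
  expect_error(trinucleotide_context("C", "C", "A", "G"), "differ")
})

test_that("canonicalization is strand-symmetric for all 96 x 2 cases", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (ref in c("C", "T")) for (alt in setdiff(bases, ref))
    for (f5 in bases) for (f3 in bases) {
      fwd <- trinucleotide_context(ref, alt, f5, f3)
      rev <- trinucleotide_context(comp[ref], comp[alt], comp[f3], comp[f5])
      expect_identical(fwd$channel, rev$channel)
      # pyrimidine representation is a fixed point
      again <- trinucleotide_context(ref, alt, f5, f3)
      expect_identical(again$channel, fwd$channel)
    }
})

test_that("spectra count contexted SNVs and normalize to proportions", {
  ch <- rep(match("A[C>T]G", channel_labels()), 10)
  sp <- spectrum(ch)
  expect_equal(sum(sp$counts), 10)
  expect_equal(unname(sp$proportions[match("A[C>T]G", channel_labels())]), 1)
  expect_equal(sum(sp$proportions), 1)
  expect_error(spectrum(integer(0)), "no contexted")

  set.seed(5)
  unif <- sample.int(96L, 96000L, replace = TRUE)
  spu <- spectrum(unif)
  expect_true(all(abs(spu$proportions - 1 / 96) < 0.002))
})

test_that("deconvolution recovers planted mixtures and matches NNLS", {
  catalog <- simulate_catalog()
  w_true <- setNames(numeric(30), colnames(catalog))
  w_true[c("Signature.2", "Signature.13")] <- c(0.7, 0.3)
  ch <- simulate_spectra(10000, catalog, w_true, seed = 17)
  sp <- spectrum(ch)
  exposure <- deconvolve(sp, catalog)
  expect_lt(abs(exposure$weights[["Signature.2"]] - 0.7), 0.05)
  expect_lt(abs(exposure$weights[["Signature.13"]] - 0.3), 0.05)
  expect_lt(sum(exposure$weights[setdiff(names(w_true),
                                         c("Signature.2", "Signature.13"))]),
            0.1)
  # non-negative least squares as an independent oracle
  nnls <- pracma::lsqnonneg(catalog, as.numeric(sp$proportions))$x
  expect_lt(abs(nnls[2] - 0.7), 0.05)
  expect_lt(abs(nnls[13] - 0.3), 0.05)
})

test_that("a pure catalog profile is fit almost entirely by itself", {
  catalog <- simulate_catalog()
  counts <- round(catalog[, "Signature.2"] * 1000)
  sp <- list(counts = counts, proportions = counts / sum(counts),
             total = sum(counts))
  class(sp) <- "mutation_spectrum"
  ex <- deconvolve(sp, catalog)
  expect_gte(ex$weights[["Signature.2"]], 0.99)
  expect_equal(sum(ex$weights) - ex$weights[["Signature.2"]], 0)
})

test_that("mass off the catalog support lands in unknown/other", {
  catalog <- matrix(0, 96, 2, dimnames = list(channel_labels(),
                                              c("S1", "S2")))
  catalog[1:10, 1] <- 1 / 10
  catalog[11:20, 2] <- 1 / 10
  sp <- numeric(96); sp[96] <- 500
  ex <- deconvolve(sp, catalog)
  expect_gt(ex$unknown, 0.95)
})

test_that("greedy error never exceeds the best single-signature error", {
  catalog <- simulate_catalog()
  set.seed(23)
  w <- stats::runif(30); w <- w / sum(w)
  ch <- simulate_spectra(5000, catalog, w, seed = 24)
  sp <- spectrum(ch)
  ex <- deconvolve(sp, catalog, min_weight = 0)
  single_err <- apply(catalog, 2L, function(ck) {
    d <- sum(ck * sp$proportions) / sum(ck^2)
    sum((sp$proportions - min(1, max(0, d)) * ck)^2)
  })
  expect_lte(ex$error, min(single_err) + 1e-12)
})

test_that("APOBEC fraction counts the TCW motif channels", {
  tca <- match("T[C>T]A", channel_labels())
  expect_equal(apobec_fraction(rep(tca, 5))$fraction, 1)
  other <- match("A[C>A]A", channel_labels())
  expect_equal(apobec_fraction(rep(other, 5))$fraction, 0)
  mixed <- c(rep(tca, 300), rep(other, 700))
  expect_equal(apobec_fraction(mixed)$fraction, 0.30)
  expect_true(is.na(apobec_fraction(integer(0))$fraction))
})

test_that("pooled two-proportion z-test matches the chi-square identity", {
  eq <- two_proportion_test(30, 100, 30, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  tp <- two_proportion_test(50, 100, 10, 100)
  cs <- suppressWarnings(prop.test(c(50, 10), c(100, 100), correct = FALSE))
  expect_equal(tp$z^2, unname(cs$statistic), tolerance = 1e-9)
  expect_equal(tp$p, cs$p.value, tolerance = 1e-9)

  expect_warning(two_proportion_test(1, 2, 0, 1), "approximation")
  expect_error(two_proportion_test(5, 0, 1, 10), ">= 1")
  # log-space p stays reportable past double underflow
  huge <- two_proportion_test(90000, 100000, 10000, 100000)
  expect_true(is.finite(huge$log10_p))
  expect_lt(huge$log10_p, -300)
})

test_that("the shipped synthetic catalog file matches the generator", {
  path <- system.file("extdata", "synthetic_signature_catalog.tsv",
                      package = "clonephene")
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$channel
  expect_equal(m, simulate_catalog(), tolerance = 1e-12)
})
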