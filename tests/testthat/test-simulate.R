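test_that("generators are bit-reproducible given a seed", {
  cfg <- bottleneck_patient_config(30)
  expect_identical(simulate_variants(cfg, seed = 5),
                   simulate_variants(cfg, seed = 5))
  cells <- data.frame(subclone = "s", timepoint = "pre", n = 5)
  expect_identical(simulate_cells(n_genes = 200, cells = cells, seed = 2),
                   simulate_cells(n_genes = 200, cells = cells, seed = 2))
  drugs <- list(a = list(top = 100, bottom = 0, ic50 = 2, hill = 1),
                b = list(top = 100, bottom = 0, ic50 = 4, hill = 1))
  expect_identical(simulate_plate(drugs, doses = 1:4, seed = 9),
                   simulate_plate(drugs, doses = 1:4, seed = 9))
})

test_that("expected raw VAF is purity x CCF / ploidy factor", {
  clusters <- data.frame(cluster = "A", parent = "root", n_mut = 4000)
  cfg <- sim_config(clusters, ccf = matrix(1, 1, 1, dimnames = list("A", "t1")),
                    purity = 0.5, depth_mean = 60, n_germline = 0)
  sim <- simulate_variants(cfg, seed = 11)
  expect_equal(mean(sim$variants$raw_vaf), 0.25, tolerance = 0.01)
  # germline SNPs sit at VAF 0.5 regardless of purity
  cfg2 <- sim_config(clusters, matrix(1, 1, 1, dimnames = list("A", "t1")),
                     purity = 0.5, n_germline = 2000)
  sim2 <- simulate_variants(cfg2, seed = 12)
  germ <- sim2$variants[sim2$variants$germline_vaf == 0.5, ]
  expect_equal(mean(germ$raw_vaf), 0.5, tolerance = 0.02)
})

test_that("tree-violating CCFs are a config error", {
  clusters <- data.frame(cluster = c("A", "B", "C"),
                         parent = c("root", "A", "A"), n_mut = 10)
  ccf <- matrix(c(0.5, 0.4, 0.3), 3, 1, dimnames = list(c("A", "B", "C"), "t1"))
  expect_error(sim_config(clusters, ccf, purity = 1), "exceed")
  ccf_ok <- matrix(c(0.8, 0.4, 0.3), 3, 1,
                   dimnames = list(c("A", "B", "C"), "t1"))
  expect_s3_class(sim_config(clusters, ccf_ok, purity = 1), "sim_config")
})

test_that("observed bulk copy mixes tumor and normal states", {
  pr <- simulate_copy_profile(20000, purity = 0.6, noise_sd = 1e-4, seed = 4)
  obs3 <- pr$observed[pr$true_copy == 3]
  expect_equal(mean(obs3), 0.6 * 3 + 0.4 * 2, tolerance = 1e-3)
})

test_that("simulated spectra converge to the mixture profile", {
  catalog <- simulate_catalog()
  w <- setNames(numeric(30), colnames(catalog))
  w["Signature.2"] <- 1
  ch <- simulate_spectra(1e6, catalog, w, seed = 21)
  emp <- tabulate(ch, 96) / 1e6
  expect_lt(sum(abs(emp - catalog[, "Signature.2"])), 0.01)

  w2 <- setNames(numeric(30), colnames(catalog))
  w2[c("Signature.2", "Signature.13")] <- 0.5
  ch2 <- simulate_spectra(2e5, catalog, w2, seed = 22)
  emp2 <- tabulate(ch2, 96) / 2e5
  target <- 0.5 * catalog[, "Signature.2"] + 0.5 * catalog[, "Signature.13"]
  expect_lt(sum(abs(emp2 - target)), 0.02)

  expect_identical(simulate_spectra(0, catalog, w, seed = 1), integer(0))
  w_bad <- w; w_bad[1] <- -0.1; w_bad[2] <- 1.1
  expect_error(simulate_spectra(10, catalog, w_bad, seed = 1), "negative")
})

test_that("the synthetic catalog is a valid signature catalog", {
  catalog <- simulate_catalog()
  expect_equal(dim(catalog), c(96L, 30L))
  expect_true(all(catalog >= 0))
  expect_equal(colSums(catalog), setNames(rep(1, 30), colnames(catalog)),
               tolerance = 1e-9)
  expect_identical(catalog, simulate_catalog())  # deterministic
})

test_that("CNA blocks scale expression and dropout behaves at extremes", {
  cells <- data.frame(subclone = c("a", "b"), timepoint = "pre", n = 40)
  blocks <- data.frame(subclone = "a", chrom = "chr1", from = 1, to = 100,
                       copy = 3)
  sc <- simulate_cells(n_genes = 500, n_chrom = 5, cells = cells,
                       cna_blocks = blocks, dropout = 0, seed = 6)
  in_block <- sc$genes$chrom == "chr1"
  a_cells <- sc$cells$cell[sc$cells$subclone == "a"]
  b_cells <- sc$cells$cell[sc$cells$subclone == "b"]
  ratio <- mean(sc$expr[in_block, a_cells]) / mean(sc$expr[in_block, b_cells])
  expect_equal(ratio, 1.5, tolerance = 0.15)

  all_out <- simulate_cells(n_genes = 100, cells = cells, dropout = 1,
                            seed = 6)
  expect_true(all(all_out$expr == 0))

  bad <- data.frame(subclone = "a", chrom = "chr1", from = 1, to = 1000,
                    copy = 3)
  expect_error(simulate_cells(n_genes = 500, cells = cells,
                              cna_blocks = bad, seed = 1), "outside")
})

test_that("noiseless plates reproduce the 4PL and Bliss ground truth", {
  drugs <- list(a = list(top = 100, bottom = 0, ic50 = 2, hill = 1),
                b = list(top = 100, bottom = 0, ic50 = 4, hill = 1))
  sim <- simulate_plate(drugs, doses = c(0.5, 1, 2, 4, 8), noise_sd = 0,
                        excess = 0, seed = 8)
  nv <- normalize_viability(sim$plate)
  # single agent at its IC50 sits at 50%
  expect_equal(nv$viability[nv$drug == "a" & nv$dose == 2],
               rep(50, 4), tolerance = 1e-9)
  # combination equals the Bliss expectation exactly
  ia <- 1 - nv$viability[nv$drug == "a" & nv$replicate == 1] / 100
  ib <- 1 - nv$viability[nv$drug == "b" & nv$replicate == 1] / 100
  icomb <- 1 - nv$viability[nv$drug == "a+b" & nv$replicate == 1] / 100
  expect_equal(icomb, bliss_expected(ia, ib), tolerance = 1e-9)
  expect_error(simulate_plate(drugs, doses = c(-1, 2), seed = 1), "negative")
})
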