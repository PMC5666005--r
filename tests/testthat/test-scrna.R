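test_that("QC boundaries follow the strict fewer-than rule", {
  cells <- data.frame(cell = c("a", "b", "c", "d"),
                      genes_detected = c(1700, 1699, 5000, 4000),
                      mapped_reads = c(150000, 200000, 149999, 151000))
  out <- qc_filter(cells)
  expect_identical(out$pass, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("windowed tracks are flat for reference-like and scaled cells", {
  fx <- scrna_fixture(seed = 13, dropout = 0)
  sc <- fx$sc
  normals <- sc$cells$cell[sc$cells$subclone == "normal"]
  ref <- sc$expr[, normals]
  # a pseudo-cell equal to the reference mean (in log space) has a ~0 track
  ref_mean_tpm <- 2^rowMeans(log2(ref + 1)) - 1
  probe <- cbind(flat = ref_mean_tpm, doubled = 2 * ref_mean_tpm)
  prof <- suppressWarnings(
    infer_cell_cna(probe, ref, sc$genes, w = 101))
  expect_lt(max(abs(prof$track[, "flat"])), 0.02)
  # global scaling is removed by median centering: no false CNA
  expect_lt(max(abs(prof$track[, "doubled"])), 0.02)
})

test_that("moving averages equal brute-force window sums exactly", {
  set.seed(31)
  x <- rnorm(300)
  w <- 101L
  ma <- clonephene:::moving_average(x, w)
  h <- (w - 1L) %/% 2L
  for (i in c(51L, 150L, 250L)) {
    expect_equal(ma[i], mean(x[(i - h):(i + h)]), tolerance = 1e-12)
  }
  expect_true(all(is.na(ma[1:h])))
})

test_that("a scaled gene block produces a positive interior track signal", {
  fx <- scrna_fixture(seed = 19)
  sc <- fx$sc
  normals <- sc$cells$cell[sc$cells$subclone == "normal"]
  tumor <- sc$cells$cell[sc$cells$subclone != "normal"]
  prof <- infer_cell_cna(sc$expr[, tumor], sc$expr[, normals], sc$genes)
  surv <- sc$cells$cell[sc$cells$subclone == "surv"]
  interior <- prof$genes$chrom == "chr1" &
    prof$genes$window_start >= 1e5 & prof$genes$window_end <= 249000
  flank <- prof$genes$chrom == "chr5"
  in_sig <- colMeans(prof$track[interior, surv, drop = FALSE])
  fl_sig <- colMeans(prof$track[flank, surv, drop = FALSE])
  expect_lt(stats::t.test(in_sig, fl_sig)$p.value, 0.01)
  expect_gt(mean(in_sig), mean(fl_sig))
})

test_that("chromosomes shorter than the window are skipped with a warning", {
  cells <- data.frame(subclone = "a", timepoint = "pre", n = 12)
  sc <- simulate_cells(n_genes = 150, n_chrom = 3, cells = cells,
                       dropout = 0, seed = 3)
  w <- capture_warnings(
    expect_error(infer_cell_cna(sc$expr, sc$expr, sc$genes, w = 101),
                 "full window"))
  expect_true(all(grepl("fewer than", w)))
  expect_length(w, 3L)  # one warning per skipped chromosome
})

test_that("region dynamics classify survivor / disappearing / uninformative", {
  expect_identical(classify_dynamics(c(2.2, 3.0), 2, 3)$label, "survivor")
  expect_identical(classify_dynamics(c(2.5, 2.0), 2, 3)$label, "disappearing")
  expect_identical(classify_dynamics(c(2.0, 2.0), 2, 3)$label,
                   "uninformative")
  expect_error(classify_dynamics(2.5), "two timepoints")
})

test_that("cells are assigned to subclones from informative CNA regions", {
  fx <- scrna_fixture(seed = 7)
  sc <- fx$sc
  normals <- sc$cells$cell[sc$cells$subclone == "normal"]
  tumor <- sc$cells$cell[sc$cells$subclone != "normal"]
  prof <- infer_cell_cna(sc$expr[, tumor], sc$expr[, normals], sc$genes)
  pre <- sc$cells$cell[sc$cells$timepoint == "pre" &
                         sc$cells$subclone != "normal"]
  asg <- assign_cells(prof, fx$regions, pre_cells = pre)
  truth <- ifelse(sc$cells$subclone[match(asg$cell, sc$cells$cell)] == "surv",
                  "survivor", "disappearing")
  expect_gte(mean(asg$label == truth), 0.95)
  expect_lte(mean(asg$label == "ambiguous"), 0.05)
  # determinism: identical cells never split across labels
  expect_identical(asg$label,
                   assign_cells(prof, fx$regions, pre_cells = pre)$label)
  no_regions <- fx$regions
  no_regions$label <- "uninformative"
  expect_warning(amb <- assign_cells(prof, no_regions, pre_cells = pre),
                 "ambiguous")
  expect_true(all(amb$label == "ambiguous"))
})

test_that("SNV validation enforces the coverage and max-VAF rules", {
  counts <- data.frame(
    cell = c("c1", "c2", "c3", "c1", "c2", "c1"),
    snv = c("s_good", "s_good", "s_good", "s_low", "s_low", "s_thin"),
    alt_reads = c(5L, 0L, 2L, 1L, 1L, 3L),
    total_reads = c(20L, 15L, 9L, 10L, 10L, 8L))
  # s_low: max VAF 0.1 across cells -> excluded; s_thin: never >= 10x
  assignments <- data.frame(cell = c("c1", "c2", "c3"),
                            label = c("survivor", "disappearing", "survivor"))
  rep <- snv_validate(counts, assignments)
  expect_setequal(unique(rep$calls$snv), "s_good")
  expect_equal(nrow(rep$calls), 2L)  # c3 has coverage 9: no call
  expect_identical(rep$calls$genotype[rep$calls$cell == "c1"], "mutant")
  expect_identical(rep$calls$genotype[rep$calls$cell == "c2"], "wildtype")

  none <- snv_validate(counts[counts$snv == "s_thin", ], assignments)
  expect_equal(nrow(none$calls), 0L)
  expect_match(none$reason, "no SNV")
})

test_that("planted subclonal SNVs agree with CNA-based labels", {
  fx <- scrna_fixture(seed = 29)
  sc <- fx$sc
  normals <- sc$cells$cell[sc$cells$subclone == "normal"]
  tumor <- sc$cells$cell[sc$cells$subclone != "normal"]
  prof <- infer_cell_cna(sc$expr[, tumor], sc$expr[, normals], sc$genes)
  pre <- sc$cells$cell[sc$cells$timepoint == "pre" &
                         sc$cells$subclone != "normal"]
  asg <- assign_cells(prof, fx$regions, pre_cells = pre)
  # plant an expressed SNV carried by the survivor subclone
  set.seed(30)
  is_surv <- sc$cells$subclone[match(tumor, sc$cells$cell)] == "surv"
  depth <- rpois(length(tumor), 40)
  alt <- ifelse(is_surv, rbinom(length(tumor), depth, 0.5), 0L)
  counts <- data.frame(cell = tumor, snv = "planted",
                       alt_reads = as.integer(alt),
                       total_reads = as.integer(depth))
  rep <- snv_validate(counts, asg)
  called <- rep$calls[rep$calls$label != "ambiguous", ]
  concord <- mean((called$genotype == "mutant") ==
                    (called$label == "survivor"))
  expect_gte(concord, 0.95)
})

test_that("flat cells are flagged normal, CNA-bearing cells are not", {
  set.seed(61)
  n_genes <- 400
  cna <- matrix(rnorm(n_genes * 20, 0, 0.5), n_genes, 20)
  cna[100:249, 11:20] <- cna[100:249, 11:20] + 0.6  # regional shift
  colnames(cna) <- paste0("c", 1:20)
  flags <- flag_normal_cells(cna, w = 101, n_perm = 20, seed = 5)
  # flat cells exceed their own null ~5% of the time by construction
  expect_gte(mean(flags[1:10]), 0.8)
  expect_false(any(flags[11:20]))
})
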