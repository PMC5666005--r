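## Synthetic patients with known ground truth.
##
## The generator emulates the study's measurement process: multi-timepoint
## variant read counts drawn from a known subclone tree through per-sample
## purity and binomial sequencing noise at ~60x depth; trinucleotide
## spectra drawn from known signature mixtures; single-cell expression with
## subclone-specific CNA blocks, a planted pathway shift and dropout; and
## 4PL dose-response plates with a configurable Bliss-excess interaction.

#' Build a simulation configuration
#'
#' Validates and assembles the ground truth for a synthetic patient. The
#' tree is given as a parent list over mutation clusters (parent `"root"`
#' for truncal clusters) with a clusters x timepoints CCF matrix; at every
#' timepoint the CCFs of a node's children may not sum above the node's own
#' CCF.
#'
#' @param clusters data.frame with columns `cluster`, `parent` (`"root"` or
#'   another cluster), `n_mut` (mutations per cluster).
#' @param ccf numeric matrix, clusters x timepoints, rownames matching
#'   `clusters$cluster`.
#' @param purity per-timepoint tumor purity in (0, 1].
#' @param ploidy_mode `"diploid"` (ploidy factor 2) or `"tetraploid"` (4).
#' @param depth_mean mean sequencing depth (depth ~ Poisson; default 60).
#' @param n_germline germline het SNPs simulated at expected VAF 0.5
#'   regardless of purity.
#' @param signature_mix optional named list: cluster -> signature mixture
#'   weights (summing to 1) over the catalog used by [simulate_spectra()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(clusters, ccf, purity,
                       ploidy_mode = c("diploid", "tetraploid"),
                       depth_mean = 60, n_germline = 200,
                       signature_mix = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  ccf <- as.matrix(ccf)
  stopifnot(setequal(rownames(ccf), clusters$cluster))
  ccf <- ccf[clusters$cluster, , drop = FALSE]
  if (any(ccf < 0 | ccf > 1)) stop("CCFs must lie in [0, 1]", call. = FALSE)
  if (any(purity <= 0 | purity > 1))
    stop("purities must lie in (0, 1]", call. = FALSE)
  if (length(purity) == 1L) purity <- rep(purity, ncol(ccf))
  stopifnot(length(purity) == ncol(ccf))
  parents <- setNames(clusters$parent, clusters$cluster)
  for (t in seq_len(ncol(ccf))) {
    caps <- c(root = 1, setNames(ccf[, t], clusters$cluster))
    kid_sum <- tapply(ccf[, t], factor(parents, levels = names(caps)), sum)
    kid_sum[is.na(kid_sum)] <- 0
    if (any(kid_sum > caps + 1e-9))
      stop("config error: child CCFs exceed their parent's CCF at timepoint ",
           t, call. = FALSE)
  }
  for (mix in signature_mix %||% list()) {
    if (any(mix < 0)) stop("config error: negative signature mixture weight",
                           call. = FALSE)
    if (abs(sum(mix) - 1) > 1e-9)
      stop("config error: signature mixture must sum to 1", call. = FALSE)
  }
  structure(list(clusters = clusters, ccf = ccf, purity = purity,
                 ploidy_mode = ploidy_mode, depth_mean = depth_mean,
                 n_germline = n_germline, signature_mix = signature_mix),
            class = "sim_config")
}

#' Simulate multi-timepoint variant read counts from a subclone tree
#'
#' Copy-neutral heterozygous somatic variants have expected raw VAF
#' `purity x CCF / f` (ploidy factor f); observed alternate reads are
#' Binomial(depth, VAF) at Poisson depth. Germline SNPs sit at expected
#' VAF 0.5 regardless of purity. Locus copies are drawn around the
#' copy-neutral state (contamination-adjusted scale).
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @return list with `variants` (a `variant_table`; timepoints are the
#'   samples) and `truth` (cluster label per variant, the tree parent list,
#'   the CCF matrix, purity).
#' @export
simulate_variants <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    f <- ploidy_factor(config$ploidy_mode)
    timepoints <- colnames(config$ccf) %||%
      paste0("t", seq_len(ncol(config$ccf)))
    cl <- config$clusters
    n_som <- sum(cl$n_mut)
    n_all <- n_som + config$n_germline
    cluster_of <- c(rep(cl$cluster, cl$n_mut),
                    rep("germline", config$n_germline))
    vid <- sprintf("v%05d", seq_len(n_all))
    exp_vaf_som <- config$ccf[cluster_of[seq_len(n_som)], , drop = FALSE] *
      rep(config$purity, each = n_som) / f
    exp_vaf <- rbind(exp_vaf_som,
                     matrix(0.5, config$n_germline, length(timepoints)))
    rows <- list()
    for (t in seq_along(timepoints)) {
      depth <- rpois(n_all, config$depth_mean)
      alt <- rbinom(n_all, depth, exp_vaf[, t])
      rows[[t]] <- data.frame(
        variant_id = vid, chrom = "chr1", pos = seq_len(n_all) * 100L,
        ref = "C", alt = "T", sample = timepoints[t],
        alt_reads = alt, total_reads = depth,
        germline_vaf = ifelse(cluster_of == "germline", 0.5, 0),
        locus_copy = f + rnorm(n_all, 0, 0.1),
        stringsAsFactors = FALSE)
    }
    vt <- new_variant_table(do.call(rbind, rows))
    list(variants = vt,
         truth = list(cluster = setNames(cluster_of, vid),
                      tree = setNames(cl$parent, cl$cluster),
                      ccf = config$ccf, purity = config$purity,
                      timepoints = timepoints))
  })
}

#' Simulate a gene-level absolute-copy profile at known purity
#'
#' True integer copies are sampled per gene; the observed bulk copy mixes
#' tumor and normal cells, `purity x copy + (1 - purity) x 2`, plus
#' Gaussian measurement noise.
#'
#' @param n_genes number of genes (default 5000).
#' @param purity tumor purity in (0, 1].
#' @param copy_probs probabilities of true copies 1-4.
#' @param noise_sd per-gene measurement noise SD.
#' @param seed integer seed.
#' @return list with `observed` copies, `true_copy`, `purity`.
#' @export
simulate_copy_profile <- function(n_genes = 5000, purity = 1,
                                  copy_probs = c(0.10, 0.72, 0.12, 0.06),
                                  noise_sd = 0.05, seed = 1) {
  stopifnot(purity > 0, purity <= 1, length(copy_probs) == 4L)
  with_seed(seed, {
    k <- sample(1:4, n_genes, replace = TRUE, prob = copy_probs)
    observed <- purity * k + (1 - purity) * 2 + rnorm(n_genes, 0, noise_sd)
    list(observed = observed, true_copy = k, purity = purity)
  })
}

#' Deterministic synthetic signature catalog
#'
#' Builds a synthetic 96-channel signature catalog in the standard
#' 30-signature layout for testing deconvolution without the real catalog
#' (which is not redistributed here). Three profiles are structured:
#' signature 2 and 13 analogues concentrate on the APOBEC TCW motif
#' channels (C>T and C>G respectively) and signature 3's analogue is flat
#' (the near-uniform pattern of double-strand-break repair deficiency);
#' the rest are sparse random profiles, fixed across calls.
#'
#' @param n_signatures number of profiles (default 30).
#' @return 96 x K matrix, columns named `Signature.k`, each summing to 1.
#' @export
simulate_catalog <- function(n_signatures = 30) {
  labels <- channel_labels()
  prof <- matrix(0, 96L, n_signatures,
                 dimnames = list(labels,
                                 paste0("Signature.", seq_len(n_signatures))))
  for (k in seq_len(n_signatures)) {
    prof[, k] <- with_seed(20000L + k, {
      g <- stats::rgamma(96, shape = 0.3)
      g / sum(g)
    })
  }
  if (n_signatures >= 2) {
    apo_ct <- match(c("T[C>T]A", "T[C>T]T"), labels)
    p <- rep(0.1 / 94, 96)
    p[apo_ct] <- 0.45
    prof[, 2] <- p
  }
  if (n_signatures >= 13) {
    apo_cg <- match(c("T[C>G]A", "T[C>G]T"), labels)
    p <- rep(0.1 / 94, 96)
    p[apo_cg] <- 0.45
    prof[, 13] <- p
  }
  if (n_signatures >= 3) prof[, 3] <- rep(1 / 96, 96)
  prof
}

#' Draw trinucleotide channels from a signature mixture
#'
#' Channels are sampled from the catalog-weighted channel distribution; the
#' empirical spectrum converges to the mixture profile as n grows.
#'
#' @param n number of mutations to draw.
#' @param catalog 96 x K signature matrix (columns sum to 1).
#' @param weights mixture weights over catalog columns (non-negative,
#'   summing to 1).
#' @param seed integer seed.
#' @return integer vector of channels (1-96), length n.
#' @export
simulate_spectra <- function(n, catalog, weights, seed) {
  if (any(weights < 0)) stop("config error: negative mixture weight",
                             call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("config error: mixture weights must sum to 1", call. = FALSE)
  if (n == 0L) return(integer(0))
  p <- as.numeric(as.matrix(catalog) %*% weights)
  with_seed(seed, sample.int(96L, n, replace = TRUE, prob = p))
}

#' Simulate single-cell expression with subclone CNAs and a pathway shift
#'
#' Baseline expression is log-normal per gene; genes inside a subclone's
#' CNA block are scaled by `copy / 2` for that subclone's cells; a planted
#' gene-set shift adds `shift_log2` to the log2 expression of the set's
#' genes in one subclone; dropout zeroes entries at the configured rate.
#' QC covariates (`mapped_reads`, `genes_detected`) are recorded.
#'
#' @param n_genes genes, laid out `n_chrom` chromosomes of equal size.
#' @param n_chrom chromosomes.
#' @param cells data.frame with columns `subclone`, `timepoint`, `n`
#'   (cells per group).
#' @param cna_blocks optional data.frame with columns `subclone`, `chrom`,
#'   `from`, `to` (gene indices within chromosome, inclusive), `copy`.
#' @param shift_genes,shift_subclone,shift_log2 optional planted pathway
#'   shift.
#' @param dropout dropout probability per entry.
#' @param gene_mean_log2,gene_sd_log2,cell_sd_log2 baseline log-normal
#'   parameters.
#' @param seed integer seed.
#' @return list with `expr` (genes x cells TPM-like matrix), `genes`
#'   (gene, chrom, start), `cells` (cell, subclone, timepoint,
#'   mapped_reads, genes_detected).
#' @export
simulate_cells <- function(n_genes = 2000, n_chrom = 5, cells,
                           cna_blocks = NULL, shift_genes = NULL,
                           shift_subclone = NULL, shift_log2 = 0,
                           dropout = 0.2, gene_mean_log2 = 4,
                           gene_sd_log2 = 1.5, cell_sd_log2 = 0.8,
                           seed = 1) {
  per_chrom <- n_genes %/% n_chrom
  genes <- data.frame(
    gene = sprintf("g%04d", seq_len(n_genes)),
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = per_chrom,
                length.out = n_genes),
    start = rep(seq_len(per_chrom) * 1000L, length.out = n_genes),
    stringsAsFactors = FALSE)
  for (b in seq_len(nrow(cna_blocks %||% data.frame()))) {
    blk <- cna_blocks[b, ]
    if (blk$to > per_chrom || blk$from < 1L)
      stop("config error: CNA block outside gene range", call. = FALSE)
  }
  with_seed(seed, {
    mu <- rnorm(n_genes, gene_mean_log2, gene_sd_log2)
    cell_df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      data.frame(subclone = cells$subclone[i], timepoint = cells$timepoint[i],
                 stringsAsFactors = FALSE)[rep(1, cells$n[i]), ]))
    n_cells <- nrow(cell_df)
    cell_df$cell <- sprintf("cell%04d", seq_len(n_cells))
    log2_expr <- matrix(rnorm(n_genes * n_cells, 0, cell_sd_log2),
                        n_genes, n_cells) + mu
    for (b in seq_len(nrow(cna_blocks %||% data.frame()))) {
      blk <- cna_blocks[b, ]
      gidx <- which(genes$chrom == blk$chrom)[blk$from:blk$to]
      cidx <- which(cell_df$subclone == blk$subclone)
      log2_expr[gidx, cidx] <- log2_expr[gidx, cidx] + log2(blk$copy / 2)
    }
    if (!is.null(shift_genes) && shift_log2 != 0) {
      gidx <- match(shift_genes, genes$gene)
      cidx <- which(cell_df$subclone == shift_subclone)
      log2_expr[gidx, cidx] <- log2_expr[gidx, cidx] + shift_log2
    }
    expr <- 2^log2_expr
    if (dropout > 0)
      expr[matrix(runif(length(expr)) < dropout, n_genes, n_cells)] <- 0
    dimnames(expr) <- list(genes$gene, cell_df$cell)
    cell_df$mapped_reads <- round(rlnorm(n_cells, log(5e5), 0.3))
    cell_df$genes_detected <- colSums(expr > 0)
    list(expr = expr, genes = genes,
         cells = cell_df[, c("cell", "subclone", "timepoint",
                             "mapped_reads", "genes_detected")])
  })
}

#' Simulate a dose-response plate with a configurable Bliss excess
#'
#' Single agents follow 4PL curves; the equimolar combination responds at
#' the Bliss expectation of the single-agent inhibitions plus the
#' configured excess. Fibroblast background is additive and unaffected by
#' drug; Gaussian replicate noise is added to every well.
#'
#' @param drugs named list of two 4PL parameter lists
#'   (`top`, `bottom`, `ic50`, `hill`; viability percent scale).
#' @param doses nonzero doses tested (micromolar), applied per drug.
#' @param n_reps technical replicates per well (default 4).
#' @param noise_sd replicate noise SD on the percent-viability scale.
#' @param excess Bliss-excess inhibition added to the combination.
#' @param cancer_signal,fibro_signal vehicle-well luminescence of the
#'   cancer component and the fibroblast background.
#' @param combination whether to plate the equimolar combination.
#' @param seed integer seed.
#' @return list with `plate` (a `dose_response_table`) and `truth`
#'   (the 4PL parameters and excess).
#' @export
simulate_plate <- function(drugs, doses, n_reps = 4, noise_sd = 3,
                           excess = 0, cancer_signal = 2000,
                           fibro_signal = 500, combination = TRUE,
                           seed = 1) {
  stopifnot(length(drugs) == 2L)
  if (any(doses < 0)) stop("config error: negative dose", call. = FALSE)
  doses <- doses[doses > 0]
  viab <- function(p, d) four_pl(d, p$top, p$bottom, p$ic50, p$hill)
  arms <- lapply(names(drugs), function(nm)
    data.frame(drug = nm, dose = doses, viability = viab(drugs[[nm]], doses),
               stringsAsFactors = FALSE))
  if (combination) {
    ia <- pmin(1, pmax(0, 1 - viab(drugs[[1]], doses) / 100))
    ib <- pmin(1, pmax(0, 1 - viab(drugs[[2]], doses) / 100))
    icomb <- pmin(1, pmax(0, bliss_expected(ia, ib) + excess))
    arms <- c(arms, list(data.frame(
      drug = paste(names(drugs), collapse = "+"), dose = doses,
      viability = 100 * (1 - icomb), stringsAsFactors = FALSE)))
  }
  wells <- rbind(do.call(rbind, arms),
                 data.frame(drug = "vehicle", dose = 0, viability = 100,
                            stringsAsFactors = FALSE))
  with_seed(seed, {
    rows <- lapply(seq_len(n_reps), function(r) {
      noise_cf <- rnorm(nrow(wells), 0, noise_sd)
      noise_f <- rnorm(nrow(wells), 0, noise_sd)
      rbind(
        data.frame(condition = "cancer+fibroblast", drug = wells$drug,
                   dose = wells$dose, replicate = r,
                   signal = fibro_signal + cancer_signal *
                     (wells$viability + noise_cf) / 100,
                   stringsAsFactors = FALSE),
        data.frame(condition = "fibroblast-only", drug = wells$drug,
                   dose = wells$dose, replicate = r,
                   signal = fibro_signal + cancer_signal * noise_f / 100,
                   stringsAsFactors = FALSE))
    })
    plate <- do.call(rbind, rows)
    class(plate) <- c("dose_response_table", "data.frame")
    list(plate = plate, truth = list(drugs = drugs, excess = excess))
  })
}
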