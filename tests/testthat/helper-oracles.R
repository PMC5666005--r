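# Independent oracles and fixture builders shared across tests. Oracles are
# deliberately written as plain brute force, independent of the package's
# implementation paths.

# All forests over the clusters satisfying the sum rule, by enumerating every
# parent vector and filtering (no pruning, no ordering tricks). Vectorized
# over the full parent-vector grid so 100 random instances stay fast.
brute_force_trees <- function(ccf, tolerance = 0.05) {
  n <- length(ccf)
  ids <- names(ccf)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:n), n)))
  m <- nrow(grid)
  ok <- rep(TRUE, m)
  for (i in seq_len(n)) ok <- ok & grid[, i] != i   # no self-parent
  anc <- grid                                        # distance-1 ancestors
  for (step in seq_len(n)) {
    for (i in seq_len(n)) ok <- ok & anc[, i] != i   # cycle through i
    for (i in seq_len(n)) {                          # advance one step
      v <- anc[, i]
      nz <- which(v > 0L)
      v[nz] <- grid[cbind(nz, v[nz])]
      anc[, i] <- v
    }
  }
  cap <- c(1, unname(ccf))
  for (j in 0:n) {
    s <- numeric(m)
    for (i in seq_len(n)) s <- s + ccf[i] * (grid[, i] == j)
    ok <- ok & s <= cap[j + 1L] + tolerance
  }
  apply(grid[ok, , drop = FALSE], 1L, function(p)
    paste(c("root", ids)[p + 1L], collapse = "|"))
}

tree_key <- function(tree) paste(tree$parent, collapse = "|")

# Literal running-sum ssGSEA, one position at a time.
ssgsea_oracle <- function(expr, gene_sets, tau = 0.25) {
  N <- nrow(expr)
  out <- matrix(NA_real_, length(gene_sets), ncol(expr),
                dimnames = list(names(gene_sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE)
    ranked_genes <- rownames(expr)[ord]
    rank_weight <- (N:1)^tau
    for (s in seq_along(gene_sets)) {
      in_set <- ranked_genes %in% gene_sets[[s]]
      n_set <- sum(in_set)
      p_in <- cumsum(ifelse(in_set, rank_weight, 0)) /
        sum(rank_weight[in_set])
      p_out <- cumsum(!in_set) / (N - n_set)
      out[s, j] <- sum(p_in - p_out)
    }
  }
  out
}

# KDE mode evaluated from first principles on a grid.
kde_mode_oracle <- function(x, from, to, by) {
  bw <- stats::bw.nrd0(x)
  grid <- seq(from, to, by = by)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, x, bw)), numeric(1))
  grid[which.max(dens)]
}

# Small reference FASTA written to a temp file; returns its path.
write_test_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}

# Wide variant TSV from a per-sample counts specification.
write_test_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal VCF with per-sample AD fields.
write_test_vcf <- function(records, samples,
                           path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# A four-timepoint synthetic patient shaped like a treated tumor: a truncal
# cluster, three post-treatment subclones (one parental lineage A, one dying
# branch B, one bottleneck C inside A that sweeps to CCF 1). Each cluster
# has a distinct cross-timepoint presence pattern, and co-presence at the
# middle timepoints pins every ancestry relation, so the merged history is
# unique.
bottleneck_patient_config <- function(n_mut = 200) {
  clusters <- data.frame(
    cluster = c("TR", "A", "B", "C"),
    parent = c("root", "TR", "A", "A"),
    n_mut = n_mut, stringsAsFactors = FALSE)
  ccf <- rbind(TR = c(1, 1, 1, 1),
               A = c(0, 0.85, 1, 1),
               B = c(0, 0.35, 0, 0),
               C = c(0, 0, 0.5, 1))
  colnames(ccf) <- paste0("t", 1:4)
  sim_config(clusters, ccf, purity = c(1, 1, 1, 1), depth_mean = 60,
             n_germline = 100)
}

# expected presence patterns (VAF >= 0.05) for the config above
bottleneck_patterns <- c(TR = "1111", A = "0111", B = "0100", C = "0011")

# Two-subclone single-cell fixture: survivor and disappearing subclones,
# each with two 150-gene 1.5x CNA blocks on distinct chromosomes (tumor
# subclones in this setting carry several co-occurring subclonal CNAs),
# plus normal cells serving as the copy-number reference.
scrna_fixture <- function(seed = 7, dropout = 0.2) {
  cells <- data.frame(subclone = c("surv", "dis", "normal", "surv", "normal"),
                      timepoint = c("pre", "pre", "pre", "post", "post"),
                      n = c(50, 50, 20, 100, 20))
  blocks <- data.frame(subclone = c("surv", "surv", "dis", "dis"),
                       chrom = c("chr1", "chr3", "chr2", "chr4"),
                       from = 100, to = 249, copy = 3)
  sc <- simulate_cells(n_genes = 2000, n_chrom = 5, cells = cells,
                       cna_blocks = blocks, dropout = dropout, seed = seed)
  regions <- data.frame(region = paste0("r", 1:4),
                        chrom = c("chr1", "chr3", "chr2", "chr4"),
                        start = 1e5, end = 249000,
                        label = rep(c("survivor", "disappearing"), each = 2),
                        direction = "gain", stringsAsFactors = FALSE)
  list(sc = sc, regions = regions)
}
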