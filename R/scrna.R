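## Single-cell CNA inference and subclone assignment.
##
## Large-scale copy-number alterations leave a footprint in expression:
## averaging log-expression deviations from a normal reference over a
## 101-gene genomic window smooths gene-level noise into a per-cell
## relative-copy track. Regions whose bulk copy dynamics mark them as
## belonging to the surviving or the disappearing subclone then let each
## cell be assigned to a subclone.

#' Quality-control filter for single cells
#'
#' Cells expressing fewer than `min_genes` genes or with fewer than
#' `min_reads` mapped reads are excluded; cells exactly at a boundary pass.
#'
#' @param cells data.frame with columns `cell`, `genes_detected`,
#'   `mapped_reads`.
#' @param min_genes,min_reads inclusive lower bounds (defaults 1700 genes
#'   and 150,000 reads).
#' @return the input with a logical `pass` column added.
#' @export
qc_filter <- function(cells, min_genes = 1700, min_reads = 150000) {
  stopifnot(all(c("genes_detected", "mapped_reads") %in% names(cells)))
  cells$pass <- cells$genes_detected >= min_genes &
    cells$mapped_reads >= min_reads
  cells
}

#' Infer per-cell relative-copy tracks from expression
#'
#' For each cell and gene, the signal is `log2(TPM + 1)` minus the mean of
#' the same quantity over the normal reference cells, clipped to +/- `clip`.
#' Within each chromosome (genes in genomic order) a centered moving average
#' of width `w` is taken; only genes with a full window are kept. Each
#' cell's track median is then subtracted, so global library-size or
#' ploidy shifts produce no regional signal.
#'
#' @param expr genes x cells non-negative TPM matrix (gene rownames).
#' @param reference normal-reference matrix with the same genes (>= 10
#'   cells).
#' @param gene_order data.frame with columns `gene`, `chrom`, `start`
#'   giving the genomic order of (at least) the genes used.
#' @param w window width in genes (odd; default 101).
#' @param clip deviation cap before averaging.
#' @return object of class `cell_cna_profile`: list with `track` (windowed
#'   genes x cells matrix) and `genes` (the genes retained, in order, with
#'   the coordinate span of each gene's window). Chromosomes with fewer
#'   than `w` genes are skipped with a warning.
#' @export
infer_cell_cna <- function(expr, reference, gene_order, w = 101L,
                           clip = 3) {
  stopifnot(w %% 2L == 1L)
  if (ncol(reference) < 10L)
    stop("need at least 10 normal reference cells", call. = FALSE)
  gene_order <- gene_order[order(gene_order$chrom, gene_order$start), ]
  genes <- intersect(gene_order$gene, rownames(expr))
  genes <- genes[genes %in% rownames(reference)]
  gene_order <- gene_order[match(genes, gene_order$gene), ]
  ref_mean <- rowMeans(log2(reference[genes, , drop = FALSE] + 1))
  r <- log2(expr[genes, , drop = FALSE] + 1) - ref_mean
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  track_rows <- list()
  keep_genes <- list()
  for (chr in unique(gene_order$chrom)) {
    idx <- which(gene_order$chrom == chr)
    if (length(idx) < w) {
      warning("chromosome ", chr, " has fewer than ", w, " genes; skipped")
      next
    }
    sm <- apply(r[idx, , drop = FALSE], 2L, moving_average, w = w)
    full <- !is.na(sm[, 1])
    track_rows[[chr]] <- sm[full, , drop = FALSE]
    gk <- gene_order[idx[full], ]
    h <- (w - 1L) %/% 2L
    centers <- which(full)
    gk$window_start <- gene_order$start[idx[centers - h]]
    gk$window_end <- gene_order$start[idx[centers + h]]
    keep_genes[[chr]] <- gk
  }
  if (length(track_rows) == 0L)
    stop("no chromosome had enough genes for a full window", call. = FALSE)
  track <- do.call(rbind, track_rows)
  genes_kept <- do.call(rbind, keep_genes)
  rownames(track) <- genes_kept$gene
  colnames(track) <- colnames(expr)
  track <- sweep(track, 2L, apply(track, 2L, median))
  structure(list(track = track, genes = genes_kept),
            class = "cell_cna_profile")
}

#' Classify a CNA region's dynamics across timepoints
#'
#' A region whose bulk mean copy starts strictly between the baseline and
#' the fully-altered state and then moves toward the altered state by at
#' least `delta` marks the surviving subclone (e.g. 2.2 pre-treatment to
#' 3.0 post); one that returns toward baseline by at least `delta` marks a
#' disappearing subclone (e.g. 2.5 to 2.0). Anything else is
#' uninformative.
#'
#' @param copies per-timepoint bulk mean absolute copy (>= 2 values; the
#'   first and last are compared).
#' @param base_copy,altered_copy copy states without/with the alteration.
#' @param delta minimum copy movement to call a direction.
#' @return list with `label` (`"survivor"`, `"disappearing"`, or
#'   `"uninformative"`), `pre`, `post`.
#' @export
classify_dynamics <- function(copies, base_copy = 2, altered_copy = 3,
                              delta = 0.3) {
  if (length(copies) < 2L)
    stop("need at least two timepoints to classify dynamics", call. = FALSE)
  pre <- copies[1]
  post <- copies[length(copies)]
  lo <- min(base_copy, altered_copy)
  hi <- max(base_copy, altered_copy)
  toward_altered <- (post - pre) * sign(altered_copy - base_copy)
  label <- if (pre > lo && pre < hi && toward_altered >= delta) "survivor"
  else if (pre > lo && pre < hi && -toward_altered >= delta) "disappearing"
  else "uninformative"
  list(label = label, pre = pre, post = post)
}

#' Assign single cells to survivor or disappearing subclones
#'
#' Per informative region, each cell's mean track signal is compared with a
#' two-component Gaussian split of the pre-treatment cells' region means:
#' the threshold is the midpoint of the component means, with a dead zone
#' of +/- `dead_zone_frac` x component separation scored as ambiguous. A
#' cell carrying a survivor-labelled CNA votes survivor (and vice versa);
#' the cell's label is the majority over informative regions, with ties or
#' no informative regions giving `"ambiguous"`.
#'
#' @param profile a `cell_cna_profile`.
#' @param regions data.frame with columns `region`, `chrom`, `start`,
#'   `end` (gene coordinates, 1-based inclusive), `label` (`"survivor"` or
#'   `"disappearing"`), and `direction` (`"gain"` or `"loss"`).
#' @param pre_cells cell identifiers of the pre-treatment sample used to
#'   fit the split.
#' @param dead_zone_frac half-width of the ambiguous band, as a fraction of
#'   the fitted component separation.
#' @return data.frame with one row per cell: `cell`, `label`, and one
#'   per-region evidence column (`+1` carrier, `-1` non-carrier, `0`
#'   ambiguous).
#' @export
assign_cells <- function(profile, regions, pre_cells,
                         dead_zone_frac = 0.25) {
  regions <- regions[regions$label %in% c("survivor", "disappearing"), ,
                     drop = FALSE]
  if (nrow(regions) == 0L) {
    warning("no survivor- or disappearing-labelled regions; ",
            "all cells ambiguous")
    return(data.frame(cell = colnames(profile$track), label = "ambiguous",
                      stringsAsFactors = FALSE))
  }
  track <- profile$track
  genes <- profile$genes
  cells <- colnames(track)
  votes <- matrix(0, length(cells), nrow(regions),
                  dimnames = list(cells, regions$region))
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    # prefer windows entirely inside the region: edge windows mix carrier
    # and neutral genes and dilute the signal
    in_region <- genes$chrom == rg$chrom &
      genes$window_start >= rg$start & genes$window_end <= rg$end
    if (!any(in_region))
      in_region <- genes$chrom == rg$chrom & genes$start >= rg$start &
        genes$start <= rg$end
    if (!any(in_region)) next
    s <- colMeans(track[in_region, , drop = FALSE])
    fit <- Mclust(s[pre_cells], G = 2L, modelNames = "E",
                          verbose = FALSE)
    mu <- sort(fit$parameters$mean)
    mid <- mean(mu)
    dead <- dead_zone_frac * diff(mu)
    carrier_high <- (rg$direction %||% "gain") == "gain"
    carrier <- ifelse(abs(s - mid) <= dead, 0,
                      ifelse((s > mid) == carrier_high, 1, -1))
    votes[, k] <- if (rg$label == "survivor") carrier else -carrier
  }
  score <- rowSums(votes)
  label <- ifelse(score > 0, "survivor",
                  ifelse(score < 0, "disappearing", "ambiguous"))
  out <- data.frame(cell = cells, label = label, votes,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate cell subclone assignments with expressed SNVs
#'
#' SNVs whose scRNA-Seq VAF never exceeds `min_max_vaf` in any cell are not
#' analyzed. For the remaining SNVs, a cell is called only when its
#' coverage is at least `min_cov`; a call is mutant when at least one
#' alternate read is seen. Returns the cross-tabulation of genotype calls
#' against the CNA-based subclone labels.
#'
#' @param counts data.frame with columns `cell`, `snv`, `alt_reads`,
#'   `total_reads`.
#' @param assignments data.frame from [assign_cells()] (columns `cell`,
#'   `label`).
#' @param min_cov minimum coverage to make a call (inclusive).
#' @param min_max_vaf an SNV is analyzed only if its VAF exceeds this in at
#'   least one cell (strict).
#' @return list with `calls` (per qualifying cell x SNV genotype calls) and
#'   `table` (genotype x subclone-label counts per SNV); both empty, with a
#'   `reason`, when nothing qualifies.
#' @export
snv_validate <- function(counts, assignments, min_cov = 10,
                         min_max_vaf = 0.2) {
  vaf <- ifelse(counts$total_reads > 0,
                counts$alt_reads / counts$total_reads, NA_real_)
  max_vaf <- tapply(vaf, counts$snv, max, na.rm = TRUE)
  keep_snv <- names(max_vaf)[is.finite(max_vaf) & max_vaf > min_max_vaf]
  calls <- counts[counts$snv %in% keep_snv &
                    counts$total_reads >= min_cov, , drop = FALSE]
  if (nrow(calls) == 0L)
    return(list(calls = calls, table = NULL,
                reason = "no SNV passed the max-VAF and coverage rules"))
  calls$genotype <- ifelse(calls$alt_reads >= 1L, "mutant", "wildtype")
  calls$label <- assignments$label[match(calls$cell, assignments$cell)]
  tab <- table(snv = calls$snv, genotype = calls$genotype,
               label = calls$label)
  list(calls = calls, table = tab, reason = NULL)
}

#' Flag probable normal cells by track flatness
#'
#' Normal (non-cancer) cells have no CNAs, so their relative-copy track is
#' flat up to windowed noise. Each cell's track variance is compared with a
#' permutation null built by shuffling that cell's own gene-level
#' deviations and re-averaging: shuffling destroys regional structure while
#' preserving the per-gene noise, so a cell whose observed track variance
#' does not exceed the null's upper quantile shows no evidence of CNAs and
#' is flagged normal.
#'
#' @param deviations genes x cells matrix of clipped log-ratio deviations
#'   (the pre-smoothing signal; genes in genomic order within one
#'   chromosome suffices).
#' @param w window width used for the track.
#' @param n_perm permutations per cell.
#' @param q null quantile a cancer cell must exceed (default 0.95).
#' @param seed seed for the permutations.
#' @return logical vector, TRUE for cells flagged normal.
#' @export
flag_normal_cells <- function(deviations, w = 101L, n_perm = 20L,
                              q = 0.95, seed = 1L) {
  obs <- apply(deviations, 2L, function(x) {
    sm <- moving_average(x, w)
    stats::var(sm[!is.na(sm)])
  })
  with_seed(seed, {
    vapply(seq_len(ncol(deviations)), function(j) {
      null <- replicate(n_perm, {
        sm <- moving_average(sample(deviations[, j]), w)
        stats::var(sm[!is.na(sm)])
      })
      obs[j] <= quantile(null, q)
    }, logical(1))
  })
}
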