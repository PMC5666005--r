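## Variant table IO.
##
## The canonical on-disk TSV is wide: one row per variant with columns
## chrom, pos, ref, alt, optional variant_id and germline_vaf, one column per
## sample holding "alt/total" read counts, and optional "<sample>.copy"
## columns with the locus absolute copy number. In memory a variant table is
## long: one row per (variant, sample).

.vt_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "sample",
              "alt_reads", "total_reads", "raw_vaf", "germline_vaf",
              "locus_copy", "context", "channel96")

new_variant_table <- function(df) {
  for (col in setdiff(.vt_cols, names(df))) {
    df[[col]] <- if (col %in% c("pos", "alt_reads", "total_reads",
                                "channel96")) NA_integer_ else
      if (col %in% c("raw_vaf", "germline_vaf", "locus_copy")) NA_real_
      else NA_character_
  }
  df <- df[, .vt_cols]
  bad <- !is.na(df$alt_reads) & !is.na(df$total_reads) &
    df$alt_reads > df$total_reads
  if (any(bad))
    stop("alt_reads exceeds total_reads for variant ",
         df$variant_id[which(bad)[1]], call. = FALSE)
  if (any(df$pos < 1, na.rm = TRUE))
    stop("positions must be >= 1", call. = FALSE)
  df$raw_vaf <- ifelse(df$total_reads > 0, df$alt_reads / df$total_reads,
                       NA_real_)
  per_sample <- table(df$sample)
  if (length(unique(per_sample)) > 1L)
    stop("sample set must be identical across variants", call. = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a somatic variant table
#'
#' Reads variants with per-sample read counts from the package's wide TSV
#' layout or from a VCF v4.x file with per-sample `AD` (ref,alt depth)
#' fields. Multi-allelic VCF records are split into one row per alternate
#' allele; records lacking `AD` for any sample are dropped with a message.
#'
#' @param path file to read.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @param germline_sample for VCF input, the name of a sample whose VAF is
#'   recorded as `germline_vaf` rather than as a tumor sample.
#' @return a `variant_table`: long data.frame with one row per
#'   (variant, sample) carrying read counts, `raw_vaf`, `germline_vaf`,
#'   `locus_copy` and (after [fetch_context()]) the 96-channel context.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          germline_sample = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") read_variants_tsv(path) else
    read_variants_vcf(path, germline_sample)
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  fixed <- c("chrom", "pos", "ref", "alt")
  if (!all(fixed %in% names(df)))
    stop("TSV variant table must have columns chrom, pos, ref, alt",
         call. = FALSE)
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos) && nrow(df) > 0)
    stop_parse(path, which(is.na(pos))[1] + 1L, "malformed position")
  opt <- intersect(c("variant_id", "germline_vaf"), names(df))
  copy_cols <- grep("\\.copy$", names(df), value = TRUE)
  sample_cols <- setdiff(names(df), c(fixed, opt, copy_cols))
  if (length(sample_cols) == 0L)
    stop("no per-sample alt/total count columns found", call. = FALSE)
  vid <- if ("variant_id" %in% opt) df$variant_id else
    paste(df$chrom, pos, df$ref, df$alt, sep = ":")
  rows <- lapply(sample_cols, function(s) {
    parts <- strsplit(df[[s]], "/", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (any(!ok)) stop_parse(path, which(!ok)[1] + 1L,
                             sprintf("sample %s: expected alt/total", s))
    alt_reads <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    tot_reads <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(alt_reads) || anyNA(tot_reads))
      stop_parse(path, which(is.na(alt_reads) | is.na(tot_reads))[1] + 1L,
                 sprintf("sample %s: non-integer read count", s))
    cp <- paste0(s, ".copy")
    data.frame(variant_id = vid, chrom = df$chrom, pos = pos,
               ref = df$ref, alt = df$alt, sample = s,
               alt_reads = alt_reads, total_reads = tot_reads,
               germline_vaf = if ("germline_vaf" %in% opt)
                 as.numeric(df$germline_vaf) else NA_real_,
               locus_copy = if (cp %in% copy_cols)
                 as.numeric(df[[cp]]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  new_variant_table(do.call(rbind, rows))
}

read_variants_vcf <- function(path, germline_sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_raw))) fix_raw <- rbind(fix_raw)  # single record
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records", call. = FALSE)
  fmt <- vcf@gt[, 1]
  if (!all(grepl("AD", fmt)))
    stop("VCF format error: per-sample depth field 'AD' is required",
         call. = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)
  pos <- as.integer(fix$POS)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  dropped <- 0L
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    ad_i <- strsplit(unname(ad[i, ]), ",", fixed = TRUE)
    depths <- lapply(ad_i, function(x) suppressWarnings(as.integer(x)))
    if (any(vapply(depths, function(d) length(d) < 2L || anyNA(d),
                   logical(1)))) {
      dropped <- dropped + 1L
      next
    }
    total <- vapply(depths, sum, integer(1))
    for (a in seq_along(alts[[i]])) {
      alt_reads <- vapply(depths, function(d)
        if (length(d) >= a + 1L) d[a + 1L] else 0L, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = paste(fix$CHROM[i], pos[i], fix$REF[i],
                           alts[[i]][a], sep = ":"),
        chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i],
        alt = alts[[i]][a], sample = samples,
        alt_reads = alt_reads, total_reads = total,
        germline_vaf = NA_real_, locus_copy = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L)
    message(dropped, " VCF record(s) dropped for missing per-sample depth")
  if (length(rows) == 0L) stop("no usable VCF records", call. = FALSE)
  df <- do.call(rbind, rows)
  if (!is.null(germline_sample)) {
    if (!germline_sample %in% samples)
      stop("germline sample not in VCF: ", germline_sample, call. = FALSE)
    g <- df[df$sample == germline_sample, ]
    gv <- ifelse(g$total_reads > 0, g$alt_reads / g$total_reads, NA_real_)
    df <- df[df$sample != germline_sample, ]
    df$germline_vaf <- gv[match(df$variant_id, g$variant_id)]
  }
  new_variant_table(df)
}

#' Write a variant table to the wide TSV layout
#'
#' Inverse of [read_variants()] for TSV; `read_variants(write_variants(x))`
#' reproduces `x` exactly for integer fields and to numerical precision for
#' floats.
#'
#' @param variants a `variant_table`.
#' @param path output file.
#' @export
write_variants <- function(variants, path) {
  samples <- unique(variants$sample)
  first <- variants[!duplicated(variants$variant_id), ]
  out <- data.frame(variant_id = first$variant_id, chrom = first$chrom,
                    pos = first$pos, ref = first$ref, alt = first$alt,
                    germline_vaf = first$germline_vaf,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in samples) {
    vs <- variants[variants$sample == s, ]
    i <- match(out$variant_id, vs$variant_id)
    out[[s]] <- paste0(vs$alt_reads[i], "/", vs$total_reads[i])
    if (!all(is.na(vs$locus_copy)))
      out[[paste0(s, ".copy")]] <- vs$locus_copy[i]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach trinucleotide contexts from a reference FASTA
#'
#' Looks up the reference triplet around every SNV, checks the reference
#' allele against the FASTA, and fills the canonical pyrimidine-centered
#' context and channel via [trinucleotide_context()]. Indels are left
#' without a context.
#'
#' @param variants a `variant_table`.
#' @param fasta path to a FASTA file (a `.fai` index is created if absent).
#' @return the variant table with `context` and `channel96` filled for SNVs.
#' @export
fetch_context <- function(variants, fasta) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta, call. = FALSE)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  open(fa)
  on.exit(close(fa))
  contigs <- Rsamtools::seqinfo(fa)
  uq <- variants[!duplicated(variants$variant_id),
                 c("variant_id", "chrom", "pos", "ref", "alt")]
  is_snv <- nchar(uq$ref) == 1L & nchar(uq$alt) == 1L
  ctx <- rep(NA_character_, nrow(uq))
  chn <- rep(NA_integer_, nrow(uq))
  if (any(is_snv)) {
    snv <- uq[is_snv, ]
    lens <- GenomeInfoDb::seqlengths(contigs)[snv$chrom]
    if (anyNA(lens))
      stop("contig not in FASTA: ",
           snv$chrom[which(is.na(lens))[1]], call. = FALSE)
    if (any(snv$pos < 2L))
      stop("SNV at position 1 of its contig has no 5' flank", call. = FALSE)
    if (any(snv$pos + 1L > lens))
      stop("SNV position outside (or at the 3' edge of) its contig",
           call. = FALSE)
    gr <- GenomicRanges::GRanges(snv$chrom,
                                 IRanges::IRanges(snv$pos - 1L,
                                                  snv$pos + 1L))
    trip <- toupper(as.character(Rsamtools::scanFa(fa, gr)))
    mid <- substr(trip, 2L, 2L)
    if (any(mid != snv$ref))
      stop(sprintf("reference mismatch at %s:%d: variant says %s, FASTA says %s",
                   snv$chrom[mid != snv$ref][1], snv$pos[mid != snv$ref][1],
                   snv$ref[mid != snv$ref][1], mid[mid != snv$ref][1]),
           call. = FALSE)
    cc <- trinucleotide_context(snv$ref, snv$alt,
                                substr(trip, 1L, 1L), substr(trip, 3L, 3L))
    ctx[is_snv] <- cc$context
    chn[is_snv] <- cc$channel
  }
  i <- match(variants$variant_id, uq$variant_id)
  variants$context <- ctx[i]
  variants$channel96 <- chn[i]
  variants
}
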