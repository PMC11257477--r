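#' Gene-region scheme
#'
#' Offsets defining the four analysis regions relative to the transcription
#' start and end sites, in transcription direction, 1-based-inclusive
#' positions with the TSS (resp. TES) at offset 0. Defaults: UAS -500 to
#' -151 relative to the TSS; promoter -150 to +25 relative to the TSS;
#' transcript +26 relative to the TSS to -76 relative to the TES;
#' terminator -75 to +150 relative to the TES. With these offsets the UAS,
#' promoter and terminator are always 350, 176 and 226 bp wide.
#'
#' @param uas,promoter Offsets `c(lo, hi)` relative to the TSS.
#' @param transcript `c(lo, hi)`: `lo` relative to the TSS, `hi` relative
#'   to the TES.
#' @param terminator Offsets relative to the TES.
#' @return An object of class `"region_scheme"`.
#' @export
region_scheme <- function(uas = c(-500, -151), promoter = c(-150, 25),
                          transcript = c(26, -76), terminator = c(-75, 150)) {
  for (x in list(uas, promoter, transcript, terminator))
    if (length(x) != 2) stop("each region is a c(lo, hi) offset pair")
  structure(list(uas = uas, promoter = promoter, transcript = transcript,
                 terminator = terminator), class = "region_scheme")
}

# offsets (transcription direction, inclusive) -> genomic 0-based half-open
offset_interval <- function(anchor0, lo, hi, strand) {
  if (strand == "+") c(anchor0 + lo, anchor0 + hi + 1)
  else c(anchor0 - hi, anchor0 - lo + 1)
}

#' Absolute genomic intervals of a gene's analysis regions
#'
#' Converts the scheme's transcription-direction offsets into absolute
#' 0-based half-open intervals, mirroring minus-strand genes (their UAS
#' lies at larger coordinates). A gene too short for a nonempty transcript
#' region (fewer than 102 bp between TSS+26 and TES-76) is an error; batch
#' callers skip such genes.
#'
#' @param gene A list or one-row data frame with `seqname`, `strand`
#'   (`"+"`/`"-"`), `tss`, `tes` (0-based coordinates; for minus-strand
#'   genes `tss > tes`).
#' @param scheme A [region_scheme()].
#' @return A data frame with one row per region (`uas`, `promoter`,
#'   `transcript`, `terminator`): `region`, `seqname`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @examples
#' gene_regions(list(seqname = "chr1", strand = "+", tss = 1000, tes = 3000))
#' @export
gene_regions <- function(gene, scheme = region_scheme()) {
  tss <- gene$tss; tes <- gene$tes; strand <- gene$strand
  if (strand == "+" && tss >= tes) stop("plus-strand gene needs tss < tes")
  if (strand == "-" && tss <= tes) stop("minus-strand gene needs tss > tes")
  iv <- rbind(
    uas        = offset_interval(tss, scheme$uas[1], scheme$uas[2], strand),
    promoter   = offset_interval(tss, scheme$promoter[1],
                                 scheme$promoter[2], strand),
    transcript = if (strand == "+")
                   c(tss + scheme$transcript[1],
                     tes + scheme$transcript[2] + 1)
                 else c(tes - scheme$transcript[2],
                        tss - scheme$transcript[1] + 1),
    terminator = offset_interval(tes, scheme$terminator[1],
                                 scheme$terminator[2], strand))
  if (iv["transcript", 1] >= iv["transcript", 2])
    stop("gene too short for a nonempty transcript region")
  data.frame(region = rownames(iv), seqname = gene$seqname,
             start = iv[, 1], end = iv[, 2], strand = strand,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Length-normalised mean signal per region
#'
#' Mean signal per base pair over each interval. Intervals reaching past
#' the reference bounds are clipped with a warning.
#'
#' @param track A [coverage_track()].
#' @param regions A data frame as returned by [gene_regions()] (columns
#'   `region`, `seqname`, `start`, `end`).
#' @return The input with an added `mean` column.
#' @export
region_means <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"))
  means <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- track$values[[regions$seqname[i]]]
    if (is.null(v)) stop("unknown reference: ", regions$seqname[i])
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > length(v)) {
      warning("region clipped to reference bounds")
      s <- max(s, 0); e <- min(e, length(v))
    }
    means[i] <- if (e > s) mean(v[(s + 1):e]) else NA_real_
  }
  regions$mean <- means
  regions
}

#' Empirical region-occupancy vector from a coverage track
#'
#' The bridge from tracks to model fitting: per-gene length-normalised
#' region means, averaged across genes, assembled into the 3- or 4-element
#' vector the fit compares against (terminator reported as 3'UTR; the UAS
#' entry is dropped for TFO genes). Genes too short for the scheme are
#' skipped with a message.
#'
#' @param track A [coverage_track()] (CPM recommended).
#' @param genes Data frame of genes (`seqname`, `strand`, `tss`, `tes`).
#' @param gene_class `"STM"` (keep the UAS entry) or `"TFO"`.
#' @param scheme A [region_scheme()].
#' @return A [region_occupancy()] in CPMn units.
#' @export
track_region_occupancy <- function(track, genes, gene_class = "STM",
                                   scheme = region_scheme()) {
  gene_class <- match.arg(gene_class, c("STM", "TFO"))
  acc <- c(uas = 0, promoter = 0, transcript = 0, terminator = 0)
  n <- 0L
  for (i in seq_len(nrow(genes))) {
    reg <- tryCatch(gene_regions(genes[i, ], scheme), error = function(e) NULL)
    if (is.null(reg)) { message("skipping short gene ", i); next }
    rm_ <- region_means(track, reg)
    acc <- acc + stats::setNames(rm_$mean, rm_$region)[names(acc)]
    n <- n + 1L
  }
  if (n == 0) stop("no usable genes")
  acc <- acc / n
  vals <- c(UAS = acc[["uas"]], promoter = acc[["promoter"]],
            transcript = acc[["transcript"]], UTR3 = acc[["terminator"]])
  if (gene_class == "TFO") vals <- vals[-1]
  region_occupancy(pmax(vals, 0), gene_class = gene_class, units = "CPMn")
}

#' Read or write gene models as BED6
#'
#' Plus-strand genes are stored as `start = tss`, `end = tes + 1`;
#' minus-strand genes as `start = tes`, `end = tss + 1` (BED is 0-based
#' half-open). The round trip is lossless for id, strand and coordinates.
#'
#' @param genes Data frame with `id`, `seqname`, `strand`, `tss`, `tes`.
#' @param file Path.
#' @return `read_genes_bed` returns the genes data frame;
#'   `write_genes_bed` invisibly returns `file`.
#' @export
write_genes_bed <- function(genes, file) {
  start <- ifelse(genes$strand == "+", genes$tss, genes$tes)
  end <- ifelse(genes$strand == "+", genes$tes, genes$tss) + 1
  df <- data.frame(chrom = genes$seqname, start = start, end = end,
                   name = genes$id, score = 0, strand = genes$strand)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  data.frame(id = df$name, seqname = df$chrom, strand = df$strand,
             tss = ifelse(df$strand == "+", df$start, df$end - 1),
             tes = ifelse(df$strand == "+", df$end - 1, df$start),
             stringsAsFactors = FALSE)
}
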