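#' Metagene profile over length-normalised genes
#'
#' Average signal profile across genes, in three segments: an upstream
#' flank (TSS-anchored), the length-normalised gene body (TSS to TES) and a
#' downstream flank (TES-anchored). The order of operations is fixed:
#' replicate tracks are averaged per base pair first, then each segment of
#' each gene is divided into `nbins` bins whose per-bp mean is taken (so
#' genes of different length contribute on the same axis), then bins are
#' averaged across genes. Minus-strand genes are read in transcription
#' direction. Genes whose body is shorter than `nbins` bp, or whose flanks
#' reach past the reference, are skipped with a message.
#'
#' @param tracks A [coverage_track()] or list of replicate tracks with
#'   identical references.
#' @param genes Data frame (`seqname`, `strand`, `tss`, `tes`; 0-based).
#' @param flank Flank length in bp (default 1000).
#' @param nbins Bins per segment (default 100).
#' @return A data frame with columns `segment` (`"upstream"`, `"body"`,
#'   `"downstream"`), `bin` (1..nbins) and `signal`; the number of
#'   contributing genes is attached as `attr(, "n_genes")`.
#' @export
metagene_profile <- function(tracks, genes, flank = 1000, nbins = 100) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  if (length(tracks) < 1 || nrow(genes) < 1)
    stop("need at least one replicate track and one gene")
  avg <- tracks[[1]]$values
  if (length(tracks) > 1)
    for (k in 2:length(tracks))
      avg <- Map(`+`, avg, tracks[[k]]$values)
  avg <- lapply(avg, function(v) v / length(tracks))

  acc <- matrix(0, 3, nbins)
  n_used <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- avg[[g$seqname]]
    if (is.null(v)) next
    len <- abs(g$tss - g$tes) + 1
    if (len < nbins) { message("skipping short gene ", i); next }
    if (g$strand == "+") {
      if (g$tss - flank < 0 || g$tes + flank + 1 > length(v)) {
        message("skipping gene ", i, " near reference edge"); next
      }
      up <- v[(g$tss - flank + 1):g$tss]
      body <- v[(g$tss + 1):(g$tes + 1)]
      down <- v[(g$tes + 2):(g$tes + flank + 1)]
    } else {
      if (g$tes - flank < 0 || g$tss + flank + 1 > length(v)) {
        message("skipping gene ", i, " near reference edge"); next
      }
      up <- rev(v[(g$tss + 2):(g$tss + flank + 1)])
      body <- rev(v[(g$tes + 1):(g$tss + 1)])
      down <- rev(v[(g$tes - flank + 1):g$tes])
    }
    acc <- acc + rbind(bin_means(up, nbins), bin_means(body, nbins),
                       bin_means(down, nbins))
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable genes")
  out <- data.frame(
    segment = rep(c("upstream", "body", "downstream"), each = nbins),
    bin = rep(seq_len(nbins), 3),
    signal = as.numeric(t(acc / n_used)))
  attr(out, "n_genes") <- n_used
  out
}

bin_means <- function(x, nbins) {
  idx <- ceiling(seq_along(x) / length(x) * nbins)
  as.numeric(tapply(x, idx, mean))
}

#' Metasite profile around oriented sites
#'
#' Aligns the signal around a set of oriented sites (e.g. TATA boxes),
#' flipping minus-strand windows so every site reads left-to-right in its
#' own orientation, averages per base pair across sites, then smooths with
#' a sliding-window mean. Only windows fully inside the flank are emitted
#' (no partial windows at the edges). Sites within `flank` of a reference
#' edge are skipped with a message.
#'
#' @param track A [coverage_track()] (any units; deltas allowed).
#' @param sites Data frame with `seqname`, `pos` (0-based site coordinate)
#'   and `strand`.
#' @param flank Half-window in bp (default 250).
#' @param window,step Smoothing window and step in bp (defaults 10 and 5).
#' @return A data frame with `offset` (window-centre position relative to
#'   the site, in site orientation) and `signal`; the number of
#'   contributing sites is `attr(, "n_sites")`.
#' @export
metasite_profile <- function(track, sites, flank = 250, window = 10,
                             step = 5) {
  stopifnot(inherits(track, "coverage_track"), flank > 0)
  len <- 2 * flank + 1
  acc <- numeric(len)
  n_used <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    v <- track$values[[s$seqname]]
    if (is.null(v)) next
    if (s$pos - flank < 0 || s$pos + flank + 1 > length(v)) {
      message("skipping site ", i, " near reference edge"); next
    }
    x <- v[(s$pos - flank + 1):(s$pos + flank + 1)]
    if (s$strand == "-") x <- rev(x)
    acc <- acc + x
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable sites")
  mean_sig <- acc / n_used
  starts <- seq(1, len - window + 1, by = step)
  sm <- vapply(starts, function(j) mean(mean_sig[j:(j + window - 1)]),
               numeric(1))
  out <- data.frame(offset = starts - 1 - flank + (window - 1) / 2,
                    signal = sm)
  attr(out, "n_sites") <- n_used
  out
}
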