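#' Per-base coverage track
#'
#' Dense per-base signal over named reference sequences, with a units tag
#' that tracks the normalisation state: `"raw"` counts, `"CPM"` (counts per
#' million; for cleavage-frequency tracks this is the CPM-normalised
#' cleavage frequency, CPMn), or `"delta"` (signed difference, e.g. after
#' background subtraction).
#'
#' @param values Named list of numeric vectors, one per reference sequence,
#'   element `i` being the signal on base `i` (1-based).
#' @param units `"raw"`, `"CPM"` or `"delta"`.
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(values, units = c("raw", "CPM", "delta")) {
  units <- match.arg(units)
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stop("'values' must be a named list of per-base numeric vectors")
  values <- lapply(values, as.numeric)
  if (units != "delta" && any(vapply(values, function(v) any(v < 0),
                                     logical(1))))
    stop("raw and CPM tracks must be nonnegative")
  structure(list(values = values, units = units), class = "coverage_track")
}

#' @method print coverage_track
#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track (%s): %d sequence(s), total signal %g\n",
              x$units, length(x$values), track_total(x)))
  for (nm in names(x$values))
    cat(sprintf("  %s: %d bp\n", nm, length(x$values[[nm]])))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' Counts-per-million normalisation
#'
#' Scales a raw-count track so the genome-wide total is 10^6:
#' `value * 1e6 / total`. Scale-invariant (a depth-doubled library gives
#' the same CPM track). Applying it to an already-normalised track is an
#' error.
#'
#' @param track A raw-count [coverage_track()] with positive total.
#' @return The CPM track.
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw")
    stop("track is already normalised (units: ", track$units, ")")
  total <- track_total(track)
  if (total <= 0) stop("cannot CPM-normalise a track with zero total")
  coverage_track(lapply(track$values, function(v) v * 1e6 / total),
                 units = "CPM")
}

#' Subtract a background track
#'
#' Elementwise subtraction of a nonspecific-background track (e.g. soluble
#' MNase cleavage) from a specific track, both CPM-normalised. The result
#' may be negative and carries `units = "delta"`.
#'
#' @param specific,control CPM [coverage_track()]s over the same reference
#'   sequences and lengths.
#' @return A `"delta"` track.
#' @export
background_subtract <- function(specific, control) {
  stopifnot(inherits(specific, "coverage_track"),
            inherits(control, "coverage_track"))
  if (specific$units != "CPM" || control$units != "CPM")
    stop("both tracks must be CPM-normalised before subtraction")
  if (!identical(names(specific$values), names(control$values)) ||
      !identical(lengths(specific$values), lengths(control$values)))
    stop("tracks cover different references")
  vals <- Map(`-`, specific$values, control$values)
  structure(list(values = vals, units = "delta"), class = "coverage_track")
}

#' Read or write a coverage track as bedGraph
#'
#' Boundary I/O through `rtracklayer`; internal coordinates are dense
#' 1-based per-base vectors, bedGraph intervals are 0-based half-open.
#' Bases not covered by any bedGraph interval read as 0; on write,
#' zero-signal runs are omitted.
#'
#' @param file Path to a bedGraph file.
#' @param units Units to tag the track with on read.
#' @param seqlengths Optional named vector of reference lengths; default
#'   the largest end coordinate seen per sequence.
#' @return `read_bedgraph` returns a [coverage_track()];
#'   `write_bedgraph` invisibly returns `file`.
#' @export
read_bedgraph <- function(file, units = "raw", seqlengths = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  sn <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(seqlengths))
    seqlengths <- tapply(GenomicRanges::end(gr), sn, max)
  vals <- lapply(names(seqlengths), function(chr) {
    v <- numeric(seqlengths[[chr]])
    sel <- sn == chr
    s <- GenomicRanges::start(gr)[sel]; e <- GenomicRanges::end(gr)[sel]
    sc <- gr$score[sel]
    for (i in seq_along(s)) v[s[i]:e[i]] <- sc[i]
    v
  })
  names(vals) <- names(seqlengths)
  coverage_track(vals, units = units)
}

#' @rdname read_bedgraph
#' @param track A [coverage_track()].
#' @export
write_bedgraph <- function(track, file) {
  stopifnot(inherits(track, "coverage_track"))
  grs <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values != 0
    GenomicRanges::GRanges(chr,
                           IRanges::IRanges(start = s[keep], end = e[keep]),
                           score = r$values[keep])
  })
  gr <- do.call(c, grs)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
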