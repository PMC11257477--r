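#' Gene architecture for the transcription-cycle model
#'
#' The model gene is a row of equal-length compartments: an optional UAS
#' (enhancer) compartment, a promoter, `n_transcript_bins` transcribed-region
#' bins, and a terminator compartment reported as the 3'UTR. STM-class genes
#' (bound by sequence-specific transcription factors plus coactivators such as
#' SAGA, Mediator or SWI/SNF) recruit RNAPII at the UAS; TFO-class genes
#' ("transcription factor only") recruit RNAPII directly at the promoter and
#' have no UAS compartment.
#'
#' @param gene_class `"STM"` or `"TFO"`.
#' @param n_transcript_bins Number of transcribed-region compartments
#'   (default 10).
#' @param bin_length Compartment length in bp (default 120, so the default
#'   transcript is 1200 bp, the median yeast transcript length).
#' @return An object of class `"gene_architecture"`.
#' @examples
#' gene_architecture("STM")
#' gene_architecture("TFO", n_transcript_bins = 5)
#' @export
gene_architecture <- function(gene_class = c("STM", "TFO"),
                              n_transcript_bins = 10, bin_length = 120) {
  gene_class <- match.arg(gene_class)
  if (!is.numeric(n_transcript_bins) || n_transcript_bins < 1 ||
      n_transcript_bins != round(n_transcript_bins))
    stop("'n_transcript_bins' must be a positive integer")
  if (!is.numeric(bin_length) || bin_length <= 0)
    stop("'bin_length' must be > 0")
  structure(
    list(gene_class = gene_class,
         n_transcript_bins = as.integer(n_transcript_bins),
         bin_length = bin_length,
         has_uas = gene_class == "STM"),
    class = "gene_architecture")
}

#' @method print gene_architecture
#' @export
print.gene_architecture <- function(x, ...) {
  cat(sprintf("Gene architecture: %s (%s)\n", x$gene_class,
              if (x$has_uas) "UAS -> promoter recruitment"
              else "direct promoter recruitment"))
  cat(sprintf("  transcript: %d x %g bp bins (%g bp)\n",
              x$n_transcript_bins, x$bin_length,
              x$n_transcript_bins * x$bin_length))
  invisible(x)
}

# compartment labels, in gene order
compartment_names <- function(arch) {
  c(if (arch$has_uas) "UAS", "promoter",
    paste0("bin", seq_len(arch$n_transcript_bins)), "UTR3")
}

#' Kinetic rate set for the transcription cycle
#'
#' The ten rate constants of the transcription-cycle model. For STM genes,
#' RNAPII associates with the UAS (`k1`) and can dissociate (`k_minus1`),
#' transfers to the promoter (`k2`, reversible via `k_minus2`); `k3` (direct
#' promoter recruitment) is unset. For TFO genes, RNAPII is recruited directly
#' to the promoter (`k3`) and the four UAS rates are unset. At the promoter,
#' RNAPII awaits TFIIH (`k4`) and can dissociate meanwhile (`k_minus3`); once
#' the PIC is complete it initiates (`k5`), hops along the transcript bins at
#' the elongation speed `k6_speed`, and is released from the terminator
#' (`k7`). `k4`--`k7` are irreversible.
#'
#' @param gene_class `"STM"` or `"TFO"`.
#' @param k1,k_minus1 UAS association/dissociation rates (s^-1; STM only).
#' @param k2,k_minus2 UAS-to-promoter transfer and reversal rates (s^-1; STM
#'   only).
#' @param k3 Direct promoter recruitment rate (s^-1; TFO only).
#' @param k_minus3 Promoter dissociation rate while awaiting TFIIH (s^-1).
#' @param k4 TFIIH recruitment (PIC-completion) rate (s^-1).
#' @param k5 Initiation rate (s^-1).
#' @param k6_speed Elongation speed in bp/min (converted internally to a
#'   per-bin hop rate; see [elongation_hop_rate()]).
#' @param k7 Terminator release rate (s^-1).
#' @return An object of class `"rate_set"`.
#' @seealso [default_rates()] for the published/selected values,
#'   [published_ranges()] for the fitted functional ranges.
#' @examples
#' rate_set("TFO", k3 = 0.002, k_minus3 = 0.01, k4 = 0.05,
#'          k5 = 0.1, k6_speed = 1000, k7 = 0.037)
#' @export
rate_set <- function(gene_class = c("STM", "TFO"),
                     k1 = NA_real_, k_minus1 = NA_real_,
                     k2 = NA_real_, k_minus2 = NA_real_,
                     k3 = NA_real_, k_minus3 = 0, k4 = NA_real_,
                     k5 = NA_real_, k6_speed = NA_real_, k7 = NA_real_) {
  gene_class <- match.arg(gene_class)
  r <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
         k3 = k3, k_minus3 = k_minus3, k4 = k4, k5 = k5,
         k6_speed = k6_speed, k7 = k7)
  if (gene_class == "STM") {
    if (!is.na(r[["k3"]]))
      stop("STM rate sets leave k3 unset (no direct promoter recruitment)")
    r["k3"] <- NA_real_
  } else {
    uas_rates <- c("k1", "k_minus1", "k2", "k_minus2")
    if (any(!is.na(r[uas_rates])))
      stop("TFO rate sets leave k1, k_minus1, k2, k_minus2 unset (no UAS)")
    r[uas_rates] <- NA_real_
  }
  defined <- r[!is.na(r)]
  if (any(defined < 0)) stop("all rates must be >= 0")
  structure(list(rates = r, gene_class = gene_class), class = "rate_set")
}

#' @method print rate_set
#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("Transcription-cycle rates (%s gene)\n", x$gene_class))
  r <- x$rates[!is.na(x$rates)]
  units <- ifelse(names(r) == "k6_speed", "bp/min", "/s")
  cat(sprintf("  %-9s %g %s\n", names(r), unname(r), units), sep = "")
  invisible(x)
}

#' @method [ rate_set
#' @export
`[.rate_set` <- function(x, i) x$rates[i]

#' Default (published/selected) rate values
#'
#' Returns the selected rate values used throughout the model: UAS
#' association 0.002/s and dissociation 0.003/s, direct promoter recruitment
#' 0.002/s (TFO), initiation 0.1/s (from TFIIH residency), elongation 1000
#' bp/min, terminator release 0.037/s (0.0614/s in the `"gcn4"` context).
#' The four free rates (`k2`, `k_minus2`, `k_minus3`, `k4`) have no published
#' point value; by package convention their defaults are the midpoints of the
#' fitted functional ranges (geometric midpoint for ranges bounded away from
#' zero, arithmetic midpoint otherwise). See [published_ranges()].
#'
#' @param gene_class `"STM"` or `"TFO"`.
#' @param context `"standard"` (default) or `"gcn4"` (amino-acid-starvation
#'   re-fit, where terminator release is 0.0614/s).
#' @return A [rate_set()].
#' @export
default_rates <- function(gene_class = c("STM", "TFO"),
                          context = c("standard", "gcn4")) {
  gene_class <- match.arg(gene_class)
  context <- match.arg(context)
  rng <- published_ranges(gene_class, context)
  mid <- function(nm) {
    lo <- rng[[nm]][1]; hi <- rng[[nm]][2]
    if (lo > 0) sqrt(lo * hi) else (lo + hi) / 2
  }
  k7 <- if (context == "gcn4") 0.0614 else 0.037
  if (gene_class == "STM") {
    rate_set("STM", k1 = 0.002, k_minus1 = 0.003,
             k2 = mid("k2"), k_minus2 = mid("k_minus2"),
             k_minus3 = mid("k_minus3"), k4 = mid("k4"),
             k5 = 0.1, k6_speed = 1000, k7 = k7)
  } else {
    rate_set("TFO", k3 = 0.002, k_minus3 = mid("k_minus3"), k4 = mid("k4"),
             k5 = 0.1, k6_speed = 1000, k7 = k7)
  }
}

#' Functional ranges of the free rates
#'
#' The min--max range of each free rate across the fitted model ensemble
#' (ChEC-seq2 fits): `k2` 0.03--0.2/s, `k_minus2` 0--0.15/s, `k_minus3`
#' 0--0.03/s, `k4` 0.0075--0.09/s (standard growth) and `k2` 0.03--0.2/s,
#' `k_minus2` 0--0.04/s, `k_minus3` 0--0.03/s, `k4` 0.01--0.15/s in the
#' `"gcn4"` context. For TFO fits where `k3` is treated as free, the
#' published UAS-association range 0.0019--0.0027/s is used (no independent
#' estimate for `k3` exists).
#'
#' @inheritParams default_rates
#' @return Named list of length-2 numeric vectors `(min, max)` for the free
#'   rates of the class.
#' @export
published_ranges <- function(gene_class = c("STM", "TFO"),
                             context = c("standard", "gcn4")) {
  gene_class <- match.arg(gene_class)
  context <- match.arg(context)
  if (context == "gcn4") {
    stm <- list(k2 = c(0.03, 0.2), k_minus2 = c(0, 0.04),
                k_minus3 = c(0, 0.03), k4 = c(0.01, 0.15))
  } else {
    stm <- list(k2 = c(0.03, 0.2), k_minus2 = c(0, 0.15),
                k_minus3 = c(0, 0.03), k4 = c(0.0075, 0.09))
  }
  if (gene_class == "STM") stm
  else list(k3 = c(0.0019, 0.0027),
            k_minus3 = stm$k_minus3, k4 = stm$k4)
}

#' Convert elongation speed to a per-bin hop rate
#'
#' Elongation is specified as a speed (bp/min, published range 1000--3000)
#' and acts in the model as a per-compartment hop rate: a polymerase covers
#' one `bin_length` compartment in `bin_length / (speed/60)` seconds on
#' average.
#'
#' @param k6_speed Elongation speed in bp/min.
#' @param bin_length Compartment length in bp.
#' @return Hop rate in s^-1: `(k6_speed / 60) / bin_length`.
#' @examples
#' elongation_hop_rate(1000, 120)  # 0.1389/s, i.e. 7.2 s per 120 bp bin
#' @export
elongation_hop_rate <- function(k6_speed, bin_length) {
  if (!is.numeric(k6_speed) || any(k6_speed <= 0))
    stop("'k6_speed' must be > 0")
  if (!is.numeric(bin_length) || any(bin_length <= 0))
    stop("'bin_length' must be > 0")
  (k6_speed / 60) / bin_length
}

# numeric propensity vector in engine order, with NA -> 0
engine_rates <- function(rates, arch) {
  stopifnot(inherits(rates, "rate_set"), inherits(arch, "gene_architecture"))
  if (rates$gene_class != arch$gene_class)
    stop(sprintf("rate set is for %s but architecture is %s",
                 rates$gene_class, arch$gene_class))
  r <- rates$rates
  hop <- if (is.na(r[["k6_speed"]])) 0
         else elongation_hop_rate(r[["k6_speed"]], arch$bin_length)
  v <- c(r[["k1"]], r[["k_minus1"]], r[["k2"]], r[["k_minus2"]],
         r[["k3"]], r[["k_minus3"]], r[["k4"]], r[["k5"]], hop, r[["k7"]])
  v[is.na(v)] <- 0
  v
}
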