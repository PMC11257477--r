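#' Simulation protocol
#'
#' Bundles the ensemble-simulation settings: total simulated time per gene,
#' the recording window at the end of the run, the number of independent
#' genes averaged, and the master seed from which per-gene random substreams
#' are derived deterministically.
#'
#' @param total_time Simulated time per gene in s (default 1000).
#' @param record_window Recording window in s (default 60).
#' @param n_genes Number of independent genes (the study scale is 100,000;
#'   the desk default is 1000).
#' @param seed Master seed (non-negative integer).
#' @return An object of class `"sim_protocol"`.
#' @export
sim_protocol <- function(total_time = 1000, record_window = 60,
                         n_genes = 1000, seed = 1) {
  if (record_window > total_time)
    stop("'record_window' must not exceed 'total_time'")
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  structure(list(total_time = total_time, record_window = record_window,
                 n_genes = as.integer(n_genes), seed = as.numeric(seed)),
            class = "sim_protocol")
}

#' @method print sim_protocol
#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf(
    "Simulation protocol: %g s/gene, final %g s recorded, %d genes, seed %g\n",
    x$total_time, x$record_window, x$n_genes, x$seed))
  invisible(x)
}

#' Mean steady-state compartment occupancy over a gene ensemble
#'
#' Runs `protocol$n_genes` independent Gillespie simulations (compiled
#' engine, one deterministic random substream per gene) and averages the
#' time-weighted occupancy of each compartment over the recording window.
#' Deterministic given the protocol's master seed, and independent of
#' execution order.
#'
#' @param arch A [gene_architecture()].
#' @param rates A matching [rate_set()].
#' @param protocol A [sim_protocol()].
#' @return An object of class `"occupancy_vector"`: `mean` and `se` (named
#'   per-compartment), `n_genes`, and event-rate summaries
#'   (`initiation_rate`, `completion_rate`, per gene per second within the
#'   recording window).
#' @export
average_occupancy <- function(arch, rates, protocol = sim_protocol()) {
  stopifnot(inherits(protocol, "sim_protocol"))
  r <- engine_rates(rates, arch)
  res <- cpp_sim_occupancy(arch$has_uas, arch$n_transcript_bins, r,
                           protocol$n_genes, protocol$total_time,
                           protocol$record_window, protocol$seed)
  comp <- compartment_names(arch)
  structure(
    list(mean = stats::setNames(res$mean, comp),
         se = stats::setNames(res$se, comp),
         n_genes = res$n_genes,
         gene_class = arch$gene_class,
         initiation_rate = res$initiations_window /
           (protocol$n_genes * protocol$record_window),
         completion_rate = res$completions_window /
           (protocol$n_genes * protocol$record_window)),
    class = "occupancy_vector")
}

#' @method print occupancy_vector
#' @export
print.occupancy_vector <- function(x, digits = 4, ...) {
  cat(sprintf("Compartment occupancy (%s, %d genes)\n",
              x$gene_class, x$n_genes))
  print(round(rbind(mean = x$mean, se = x$se), digits))
  invisible(x)
}

#' Region occupancy vector
#'
#' The 3- or 4-element vector compared between model and data: mean
#' occupancy (or CPM-normalised signal) over the UAS (STM only), promoter,
#' transcribed region and 3'UTR.
#'
#' @param values Named or unnamed numeric vector of length 4 (STM order:
#'   UAS, promoter, transcript, UTR3) or 3 (TFO: promoter, transcript,
#'   UTR3).
#' @param gene_class `"STM"` or `"TFO"`; inferred from the length if
#'   missing.
#' @param units `"fraction"` (model occupancy), `"CPMn"` (empirical scale)
#'   or `"delta"` (signed change).
#' @param scaling `"raw"` or `"l2_scaled"`.
#' @return A classed named numeric vector (`"region_occupancy"`).
#' @export
region_occupancy <- function(values, gene_class = NULL,
                             units = c("fraction", "CPMn", "delta"),
                             scaling = c("raw", "l2_scaled")) {
  units <- match.arg(units)
  scaling <- match.arg(scaling)
  if (is.null(gene_class))
    gene_class <- if (length(values) == 4) "STM" else "TFO"
  gene_class <- match.arg(gene_class, c("STM", "TFO"))
  want <- if (gene_class == "STM") c("UAS", "promoter", "transcript", "UTR3")
          else c("promoter", "transcript", "UTR3")
  if (length(values) != length(want))
    stop(sprintf("%s region vectors have length %d", gene_class, length(want)))
  if (!is.null(names(values))) {
    if (!setequal(names(values), want))
      stop("unexpected region names: ", paste(names(values), collapse = ", "))
    values <- values[want]
  } else names(values) <- want
  if (units != "delta" && any(values < 0))
    stop("occupancy-derived region vectors must be nonnegative")
  structure(as.numeric(stats::setNames(values, want)),
            names = want, gene_class = gene_class, units = units,
            scaling = scaling, class = "region_occupancy")
}

#' @method print region_occupancy
#' @export
print.region_occupancy <- function(x, digits = 4, ...) {
  cat(sprintf("Region occupancy (%s, %s, %s)\n", attr(x, "gene_class"),
              attr(x, "units"), attr(x, "scaling")))
  y <- unclass(x); attributes(y) <- list(names = names(x))
  print(round(y, digits))
  invisible(x)
}

#' Collapse compartment occupancy to region occupancy
#'
#' The transcribed-region value is the arithmetic mean of the transcript
#' bins (bins are equal length, so this equals per-bp occupancy); UAS,
#' promoter and terminator pass through, with the terminator reported as the
#' 3'UTR.
#'
#' @param occ An [`occupancy_vector`][average_occupancy] (or a named numeric
#'   compartment vector).
#' @return A [region_occupancy()] in fraction units.
#' @export
aggregate_regions <- function(occ) {
  v <- if (inherits(occ, "occupancy_vector")) occ$mean else occ
  bins <- grep("^bin", names(v))
  if (length(bins) == 0) stop("no transcript bins found")
  out <- c(if ("UAS" %in% names(v)) c(UAS = unname(v[["UAS"]])),
           promoter = unname(v[["promoter"]]),
           transcript = mean(v[bins]),
           UTR3 = unname(v[["UTR3"]]))
  region_occupancy(out, units = "fraction")
}

#' Scale a model region vector to the magnitude of the data
#'
#' Multiplies the model vector by `||empirical|| / ||model||` (Euclidean
#' norms), approximating the conversion from occupancy fractions to CPM-like
#' units. Cosine similarity is invariant to this scaling; it affects
#' reporting and plotting only.
#'
#' @param model,empirical [region_occupancy()] vectors of equal length.
#' @return The scaled model vector (`scaling = "l2_scaled"`, units of the
#'   empirical vector).
#' @export
l2_scale <- function(model, empirical) {
  if (length(model) != length(empirical))
    stop("model and empirical vectors must have equal length")
  nm <- sqrt(sum(model^2))
  if (nm == 0) stop("cannot scale an all-zero model vector")
  ne <- sqrt(sum(empirical^2))
  out <- unclass(model) * (ne / nm)
  if (is.null(attr(model, "gene_class")))
    return(as.numeric(out))            # bare numeric in, bare numeric out
  region_occupancy(stats::setNames(as.numeric(out), names(model)),
                   gene_class = attr(model, "gene_class"),
                   units = attr(empirical, "units") %||% "CPMn",
                   scaling = "l2_scaled")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a region-occupancy vector as delimited text
#'
#' Plain-text interchange for region vectors: a header line and one row per
#' region with columns `region`, `value` and optionally `se`.
#'
#' @param x A [region_occupancy()].
#' @param file Path.
#' @param se Optional standard errors (same length).
#' @return `write_region_occupancy` invisibly returns `file`;
#'   `read_region_occupancy` returns a [region_occupancy()] (with an `se`
#'   attribute when present).
#' @export
write_region_occupancy <- function(x, file, se = NULL) {
  df <- data.frame(region = names(x), value = as.numeric(x))
  if (!is.null(se)) df$se <- as.numeric(se)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_region_occupancy
#' @param units,scaling Passed to [region_occupancy()] on read.
#' @export
read_region_occupancy <- function(file, units = "CPMn", scaling = "raw") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- region_occupancy(stats::setNames(df$value, df$region),
                          units = units, scaling = scaling)
  if ("se" %in% names(df)) attr(out, "se") <- stats::setNames(df$se, df$region)
  out
}
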