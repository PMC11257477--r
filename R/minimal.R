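#' Parameters of the minimal dwell-time occupancy model
#'
#' A single polymerase cycles through the gene: it dwells at the promoter
#' for `T_p` seconds on average, traverses the `transcript_length` bp coding
#' region at `v` bp/min, pauses at the terminator for `T_t` seconds, and is
#' immediately replaced at the promoter. Published ranges: promoter dwell
#' 5--20 s, elongation 1000--3000 bp/min, termination pause 5--70 s.
#'
#' @param T_p Promoter dwell time (s).
#' @param v Elongation speed (bp/min).
#' @param T_t Terminator dwell time (s).
#' @param transcript_length Coding-region length in bp (default 1200, the
#'   median yeast transcript).
#' @param bin_length Reporting bin size in bp (default 120).
#' @return An object of class `"minimal_params"`.
#' @export
minimal_params <- function(T_p, v, T_t, transcript_length = 1200,
                           bin_length = 120) {
  vals <- c(T_p = T_p, v = v, T_t = T_t,
            transcript_length = transcript_length, bin_length = bin_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all minimal-model parameters must be positive")
  if (transcript_length %% bin_length != 0)
    stop("'transcript_length' must be a multiple of 'bin_length'")
  structure(as.list(vals), class = "minimal_params")
}

#' Analytic occupancy of the minimal model
#'
#' By the renewal-reward theorem, the long-run fraction of time the
#' polymerase spends in each compartment equals that compartment's mean
#' dwell divided by the cycle time
#' `T_p + L / (v/60) + T_t`: promoter `T_p / cycle`, each transcript bin
#' `(bin_length / (v/60)) / cycle`, terminator `T_t / cycle`. The fractions
#' sum to 1.
#'
#' @param p A [minimal_params()].
#' @return Named numeric vector: `promoter`, `bin1..binN`, `terminator`.
#' @examples
#' minimal_occupancy_analytic(minimal_params(T_p = 10, v = 1000, T_t = 70))
#' @export
minimal_occupancy_analytic <- function(p) {
  stopifnot(inherits(p, "minimal_params"))
  n <- p$transcript_length / p$bin_length
  bin_time <- p$bin_length / (p$v / 60)
  cycle <- p$T_p + n * bin_time + p$T_t
  stats::setNames(c(p$T_p, rep(bin_time, n), p$T_t) / cycle,
                  c("promoter", paste0("bin", seq_len(n)), "terminator"))
}

#' Stochastic occupancy of the minimal model
#'
#' Gillespie version of [minimal_occupancy_analytic()]: exponential dwell in
#' each compartment (rate `1/T_p` at the promoter, `(v/60)/bin_length` per
#' bin, `1/T_t` at the terminator), a single recycling polymerase with no
#' exclusion interactions. Converges to the analytic fractions.
#'
#' @param p A [minimal_params()].
#' @param protocol A [sim_protocol()] (per-gene time, recording window,
#'   number of genes, master seed).
#' @return An `"occupancy_vector"`-style list with `mean`, `se` and
#'   `n_genes`.
#' @export
minimal_occupancy_stochastic <- function(p, protocol = sim_protocol()) {
  stopifnot(inherits(p, "minimal_params"), inherits(protocol, "sim_protocol"))
  n <- as.integer(p$transcript_length / p$bin_length)
  res <- cpp_sim_minimal(n, 1 / p$T_p, (p$v / 60) / p$bin_length, 1 / p$T_t,
                         protocol$n_genes, protocol$total_time,
                         protocol$record_window, protocol$seed)
  nm <- c("promoter", paste0("bin", seq_len(n)), "terminator")
  structure(list(mean = stats::setNames(res$mean, nm),
                 se = stats::setNames(res$se, nm),
                 n_genes = res$n_genes, gene_class = NA_character_,
                 initiation_rate = NA_real_, completion_rate = NA_real_),
            class = "occupancy_vector")
}

#' Compare promoter/terminator vs transcript occupancy over a dwell grid
#'
#' Evaluates the analytic minimal model over the cartesian product of
#' promoter dwell times, elongation speeds and terminator dwell times, and
#' flags, for every combination, whether the promoter (resp. terminator)
#' fraction exceeds the per-bin transcript fraction. Algebraically the
#' promoter flag is exactly `T_p * v / 60 > bin_length`. The default grid
#' `{5, 10, 15, 20} s x {1000, 2000, 3000} bp/min x {5, 70} s` spans the
#' published ranges with 24 combinations; counts are reported for whatever
#' grid is supplied.
#'
#' @param T_p,v,T_t Numeric vectors of values to combine.
#' @param transcript_length,bin_length Passed to [minimal_params()].
#' @param per_bin If `TRUE` (default) the transcript comparator is the
#'   per-bin fraction; if `FALSE`, the whole-region fraction.
#' @return A data frame (one row per combination) with the parameter
#'   values, `promoter_occ`, `bin_occ`, `terminator_occ`,
#'   `promoter_gt_transcript`, `terminator_gt_transcript`; summary counts
#'   of true flags are attached as `attr(, "counts")`.
#' @export
dwell_grid_comparison <- function(T_p = c(5, 10, 15, 20),
                                  v = c(1000, 2000, 3000),
                                  T_t = c(5, 70),
                                  transcript_length = 1200, bin_length = 120,
                                  per_bin = TRUE) {
  if (!length(T_p) || !length(v) || !length(T_t)) stop("empty dwell grid")
  grid <- expand.grid(T_p = T_p, v = v, T_t = T_t, KEEP.OUT.ATTRS = FALSE)
  n <- transcript_length / bin_length
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- minimal_params(grid$T_p[i], grid$v[i], grid$T_t[i],
                        transcript_length, bin_length)
    occ <- minimal_occupancy_analytic(p)
    bin_occ <- occ[["bin1"]]
    comparator <- if (per_bin) bin_occ else bin_occ * n
    data.frame(grid[i, , drop = FALSE],
               promoter_occ = occ[["promoter"]],
               bin_occ = bin_occ,
               terminator_occ = occ[["terminator"]],
               promoter_gt_transcript = occ[["promoter"]] > comparator,
               terminator_gt_transcript = occ[["terminator"]] > comparator)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    n = nrow(out),
    promoter_gt_transcript = sum(out$promoter_gt_transcript),
    terminator_gt_transcript = sum(out$terminator_gt_transcript))
  out
}
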