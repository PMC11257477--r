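#' Multiplicative noise model for synthetic region vectors
#'
#' Sequencing-derived region means are positive with roughly
#' scale-proportional dispersion, so synthetic vectors are perturbed by a
#' multiplicative lognormal factor (`exp(N(0, sigma^2))` per entry) plus an
#' optional additive background floor.
#'
#' @param sigma Lognormal sigma (dimensionless, default 0.1).
#' @param floor Additive background in CPMn units (default 0).
#' @param seed Seed for the noise draws.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0.1, floor = 0, seed = 1) {
  if (sigma < 0 || floor < 0) stop("'sigma' and 'floor' must be >= 0")
  structure(list(sigma = sigma, floor = floor, seed = seed),
            class = "noise_model")
}

apply_noise <- function(values, noise, draw = 1) {
  # deterministic given (noise$seed, draw); leaves the global RNG untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed + 7919 * draw)
  values * stats::rlnorm(length(values), 0, noise$sigma) + noise$floor
}

#' Synthetic gene annotation
#'
#' Places non-overlapping genes (with at least 1 kb clearance on either
#' side for flanks and the upstream UAS) on a single synthetic reference
#' sequence, with random strands and yeast-like transcript lengths, plus a
#' per-gene oriented "TATA" site 50 bp upstream of the TSS (matching the
#' TATA-to-TSS geometry of yeast promoters).
#'
#' @param n_genes Number of genes.
#' @param genome_length Reference length in bp.
#' @param seed RNG seed.
#' @param gene_length_range Transcript length range in bp (default
#'   1200--2400; the yeast median transcript is 1.2 kb).
#' @param seqname Reference name.
#' @return A list with `genes` (data frame: `id`, `seqname`, `strand`,
#'   `tss`, `tes`, `length`), `sites` (TATA data frame: `seqname`, `pos`,
#'   `strand`), `genome_length`, `seqname`, and a reproducibility
#'   `manifest`.
#' @export
synth_gene_annotation <- function(n_genes, genome_length, seed = 1,
                                  gene_length_range = c(1200, 2400),
                                  seqname = "synthI") {
  flank <- 1000
  slot <- floor(genome_length / n_genes)
  if (slot < max(gene_length_range) + 2 * flank + 2)
    stop("genes do not fit without overlap after flanks; enlarge the genome")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lens <- round(stats::runif(n_genes, gene_length_range[1],
                             gene_length_range[2]))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  jitter_max <- slot - max(gene_length_range) - 2 * flank
  starts <- (seq_len(n_genes) - 1) * slot + flank +
    floor(stats::runif(n_genes, 0, jitter_max + 1))
  tss <- ifelse(strands == "+", starts, starts + lens - 1)
  tes <- ifelse(strands == "+", starts + lens - 1, starts)
  genes <- data.frame(id = sprintf("synthg%03d", seq_len(n_genes)),
                      seqname = seqname, strand = strands,
                      tss = tss, tes = tes, length = lens,
                      stringsAsFactors = FALSE)
  sites <- data.frame(seqname = seqname,
                      pos = ifelse(strands == "+", tss - 50, tss + 50),
                      strand = strands, stringsAsFactors = FALSE)
  list(genes = genes, sites = sites, genome_length = genome_length,
       seqname = seqname,
       manifest = list(generator = "synth_gene_annotation",
                       n_genes = n_genes, genome_length = genome_length,
                       seed = seed, gene_length_range = gene_length_range))
}

#' Synthetic coverage track with known region weights
#'
#' Places `depth` reads multinomially across the analysis regions of the
#' given genes, with per-region probability proportional to
#' `weight x region length`, uniformly within each region. The returned
#' raw-count track is the ground-truth input for testing the binning and
#' normalisation stages.
#'
#' @param annotation As returned by [synth_gene_annotation()] (or a list
#'   with `genes`, `genome_length`, `seqname`).
#' @param region_weights Numeric of length 4, intensities for
#'   (uas, promoter, transcript, terminator); not all zero.
#' @param depth Total reads.
#' @param seed RNG seed.
#' @param scheme A [region_scheme()].
#' @return A raw [coverage_track()] with the generating parameters in
#'   `attr(, "manifest")`.
#' @export
synth_coverage <- function(annotation, region_weights = c(1, 4, 2, 3),
                           depth = 1e6, seed = 1, scheme = region_scheme()) {
  if (length(region_weights) != 4 || any(region_weights < 0))
    stop("'region_weights' must be 4 nonnegative intensities")
  if (all(region_weights == 0)) stop("all-zero region weights")
  if (depth <= 0) stop("'depth' must be > 0")
  genes <- annotation$genes
  regs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    gene_regions(genes[i, ], scheme)))
  w <- stats::setNames(region_weights,
                       c("uas", "promoter", "transcript", "terminator"))
  regs$weight <- w[regs$region] * (regs$end - regs$start)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_per_region <- as.numeric(stats::rmultinom(1, depth,
                                              regs$weight / sum(regs$weight)))
  v <- numeric(annotation$genome_length)
  for (i in seq_len(nrow(regs))) {
    if (n_per_region[i] == 0) next
    pos <- regs$start[i] + sample.int(regs$end[i] - regs$start[i],
                                      n_per_region[i], replace = TRUE)
    tab <- tabulate(pos, nbins = annotation$genome_length)
    v <- v + tab
  }
  vals <- stats::setNames(list(v), annotation$seqname)
  track <- coverage_track(vals, units = "raw")
  attr(track, "manifest") <- list(generator = "synth_coverage",
                                  region_weights = region_weights,
                                  depth = depth, seed = seed)
  track
}

#' Synthetic empirical-style region-occupancy vector
#'
#' Stands in for a sequencing-derived region vector: simulates the
#' transcription-cycle model at known true rates, aggregates to regions,
#' applies multiplicative lognormal noise and an optional floor, and
#' rescales to a CPMn-like magnitude (L2 norm = `scale`; the rescaling is
#' irrelevant to cosine-based fitting). The generating truth is recorded
#' in `attr(, "manifest")`.
#'
#' @param true_rates A [rate_set()] (the ground truth to be recovered).
#' @param arch Matching [gene_architecture()].
#' @param noise A [noise_model()].
#' @param protocol A [sim_protocol()].
#' @param scale Target L2 norm in CPMn-like units (default 100).
#' @return A [region_occupancy()] in CPMn units.
#' @export
synth_empirical_occupancy <- function(true_rates,
                                      arch = gene_architecture(
                                        true_rates$gene_class),
                                      noise = noise_model(),
                                      protocol = sim_protocol(),
                                      scale = 100) {
  reg <- aggregate_regions(average_occupancy(arch, true_rates, protocol))
  noisy <- apply_noise(as.numeric(reg), noise, draw = 1)
  noisy <- noisy * scale / sqrt(sum(noisy^2))
  out <- region_occupancy(stats::setNames(noisy, names(reg)),
                          gene_class = arch$gene_class, units = "CPMn")
  attr(out, "manifest") <- list(generator = "synth_empirical_occupancy",
                                true_rates = true_rates$rates,
                                gene_class = arch$gene_class,
                                sigma = noise$sigma, floor = noise$floor,
                                noise_seed = noise$seed,
                                protocol = unclass(protocol), scale = scale)
  out
}

#' Synthetic baseline/perturbation dataset
#'
#' Generates the paired dataset a perturbation experiment produces:
#' baseline and perturbed region vectors simulated with paired seeds
#' (common random numbers), converted to the CPMn scale with the single
#' factor fixed by the baseline, and noised independently; the empirical
#' change is their difference.
#'
#' @param true_rates Baseline [rate_set()].
#' @param spec The generating [perturbation()].
#' @inheritParams synth_empirical_occupancy
#' @return A list with `baseline` (CPMn [region_occupancy()]), `delta`
#'   (a `"delta_occupancy"`), and `manifest` (records the generating
#'   spec).
#' @export
synth_perturbation_dataset <- function(true_rates,
                                       spec,
                                       arch = gene_architecture(
                                         true_rates$gene_class),
                                       noise = noise_model(),
                                       protocol = sim_protocol(),
                                       scale = 100) {
  base <- aggregate_regions(average_occupancy(arch, true_rates, protocol))
  pert_rates <- apply_perturbation(true_rates, spec)
  pert <- aggregate_regions(average_occupancy(arch, pert_rates, protocol))
  sf <- scale / sqrt(sum(base^2))
  base_noisy <- apply_noise(as.numeric(base) * sf, noise, draw = 1)
  pert_noisy <- apply_noise(as.numeric(pert) * sf, noise, draw = 2)
  gene_class <- arch$gene_class
  baseline <- region_occupancy(stats::setNames(base_noisy, names(base)),
                               gene_class = gene_class, units = "CPMn")
  delta <- structure(
    list(mean = region_occupancy(
           stats::setNames(pert_noisy - base_noisy, names(base)),
           gene_class = gene_class, units = "delta"),
         se = stats::setNames(numeric(length(base)), names(base)),
         n_members = 1L, label = paste0("synthetic: ", spec$label)),
    class = "delta_occupancy")
  list(baseline = baseline, delta = delta,
       manifest = list(generator = "synth_perturbation_dataset",
                       true_rates = true_rates$rates, spec = unclass(spec),
                       gene_class = gene_class, sigma = noise$sigma,
                       floor = noise$floor, noise_seed = noise$seed,
                       protocol = unclass(protocol), scale = scale))
}
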