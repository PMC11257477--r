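#' Cosine similarity between model and empirical region vectors
#'
#' `sum(M_i E_i) / (sqrt(sum(M_i^2)) sqrt(sum(E_i^2)))`, where `i` runs over
#' the gene regions (UAS, promoter, transcript, 3'UTR). Ranges over
#' \[-1, 1\] (\[0, 1\] for nonnegative vectors) and is invariant to positive
#' rescaling of either argument, so occupancy fractions can be compared
#' directly with CPM-scale data.
#'
#' @param model,empirical Numeric vectors of equal length, neither all-zero.
#' @return The cosine similarity (dimensionless).
#' @examples
#' cosine_similarity(c(1, 2, 3, 4), c(2, 4, 6, 8))  # 1
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))        # 8/9
#' @export
cosine_similarity <- function(model, empirical) {
  if (length(model) != length(empirical))
    stop("vectors must have equal length")
  nm <- sqrt(sum(model^2)); ne <- sqrt(sum(empirical^2))
  if (nm == 0 || ne == 0)
    stop("cosine similarity is undefined for an all-zero vector")
  sum(model * empirical) / (nm * ne)
}

#' Grid specification for one free rate
#'
#' @param lower,upper Bounds (s^-1), `0 <= lower <= upper`.
#' @param n Number of points (>= 2, or exactly 1 when `lower == upper`).
#' @param spacing `"log"` (requires `lower > 0`) or `"linear"`.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(lower, upper, n = 12, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (lower < 0 || upper < lower) stop("need 0 <= lower <= upper")
  if (lower == upper) n <- 1L
  if (n < 2 && lower != upper) stop("need >= 2 points per free dimension")
  if (spacing == "log" && lower <= 0)
    stop("log spacing requires lower bound > 0")
  structure(list(lower = lower, upper = upper, n = as.integer(n),
                 spacing = spacing), class = "grid_spec")
}

grid_values <- function(spec) {
  if (spec$n == 1) return(spec$lower)
  if (spec$spacing == "log")
    exp(seq(log(spec$lower), log(spec$upper), length.out = spec$n))
  else seq(spec$lower, spec$upper, length.out = spec$n)
}

#' Default free-rate grid
#'
#' Free rates and bounds follow the fitted functional ranges (see
#' [published_ranges()]): for STM fits `k2`, `k_minus2`, `k_minus3` and `k4`
#' are free; for TFO fits `k3`, `k_minus3` and `k4`. Strictly positive
#' ranges are sampled log-uniformly; ranges whose lower bound is 0
#' (`k_minus2`, `k_minus3`) linearly including 0.
#'
#' @inheritParams default_rates
#' @param points_per_dim Grid resolution per free rate (default 12; use 6
#'   for quick desk runs).
#' @return Named list of [grid_spec()] objects.
#' @export
default_grid <- function(gene_class = c("STM", "TFO"), points_per_dim = 12,
                         context = c("standard", "gcn4")) {
  gene_class <- match.arg(gene_class)
  rng <- published_ranges(gene_class, context)
  lapply(rng, function(b)
    grid_spec(b[1], b[2], points_per_dim,
              spacing = if (b[1] > 0) "log" else "linear"))
}

# replace selected rates in a rate_set (values: named numeric)
modify_rates <- function(base, values) {
  r <- base$rates
  bad <- setdiff(names(values), names(r))
  if (length(bad)) stop("unknown rates: ", paste(bad, collapse = ", "))
  unset <- names(values)[is.na(r[names(values)])]
  if (length(unset))
    stop(sprintf("rate %s is not defined for %s genes",
                 paste(unset, collapse = ", "), base$gene_class))
  if (any(unlist(values) < 0)) stop("all rates must be >= 0")
  r[names(values)] <- unlist(values)
  out <- base
  out$rates <- r
  out
}

# canonical ordering used for tie-breaks and reporting
free_rate_order <- c("k1", "k_minus1", "k2", "k_minus2", "k3",
                     "k_minus3", "k4", "k5", "k6_speed", "k7")

#' Fit transcription-cycle rates to region occupancy by grid search
#'
#' The central fitting routine. Every combination of free-rate values on the
#' grid is simulated with the stochastic engine (common random numbers: the
#' same master seed for every grid point, so neighbouring models differ by
#' parameters, not noise), its region occupancy vector is compared with the
#' empirical vector by [cosine_similarity()], and all models exceeding the
#' similarity threshold form the reported ensemble. Per-rate functional
#' ranges are the min--max of each free rate across ensemble members. If no
#' model passes the threshold (as happens when fitting crosslinking-based
#' occupancy), the `fallback_n` best-scoring models are reported instead
#' with `selection_mode = "best_n"`.
#'
#' @param empirical A [region_occupancy()] vector (the data, `E_i`).
#' @param gene_class `"STM"` or `"TFO"`; defaults to the class of
#'   `empirical`.
#' @param grid Named list of [grid_spec()] per free rate; default
#'   [default_grid()].
#' @param fixed A [rate_set()] supplying the fixed rates (default
#'   [default_rates()]).
#' @param threshold Ensemble inclusion threshold on cosine similarity
#'   (default 0.995).
#' @param protocol A [sim_protocol()]; its seed is the common-random-numbers
#'   master seed.
#' @param arch Gene architecture (default the standard 10 x 120 bp gene).
#' @param points_per_dim Used only when `grid` is `NULL`.
#' @param fallback_n Ensemble size reported when no model passes the
#'   threshold.
#' @return An object of class `"rnapii_fit"` with components `members`
#'   (ensemble data frame: free rates, similarity), `scored` (all grid
#'   points), `ranges` (functional ranges), `best`, `selection_mode`, and
#'   the fit configuration. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' emp <- region_occupancy(c(promoter = 30, transcript = 6, UTR3 = 25),
#'                         units = "CPMn")
#' fit <- fit_transcription(emp, "TFO",
#'                          grid = default_grid("TFO", points_per_dim = 4),
#'                          protocol = sim_protocol(n_genes = 200, seed = 7))
#' print(fit)
#' }
#' @export
fit_transcription <- function(empirical, gene_class = NULL, grid = NULL,
                              fixed = NULL, threshold = 0.995,
                              protocol = sim_protocol(), arch = NULL,
                              points_per_dim = 12, fallback_n = 10) {
  cl <- match.call()
  if (is.null(gene_class)) gene_class <- attr(empirical, "gene_class")
  gene_class <- match.arg(gene_class, c("STM", "TFO"))
  if (is.null(arch)) arch <- gene_architecture(gene_class)
  if (arch$gene_class != gene_class) stop("architecture/class mismatch")
  expected_len <- if (gene_class == "STM") 4L else 3L
  if (length(empirical) != expected_len)
    stop(sprintf("empirical vector must have length %d for %s genes",
                 expected_len, gene_class))
  if (is.null(grid)) grid <- default_grid(gene_class, points_per_dim)
  if (length(grid) == 0) stop("empty grid")
  if (is.null(fixed)) fixed <- default_rates(gene_class)

  free <- intersect(free_rate_order, names(grid))
  pts <- expand.grid(lapply(grid[free], grid_values),
                     KEEP.OUT.ATTRS = FALSE)
  names(pts) <- free

  sims <- numeric(nrow(pts))
  vectors <- matrix(NA_real_, nrow(pts), expected_len)
  for (i in seq_len(nrow(pts))) {
    rs <- modify_rates(fixed, as.list(pts[i, , drop = FALSE]))
    occ <- average_occupancy(arch, rs, protocol)
    reg <- aggregate_regions(occ)
    vectors[i, ] <- as.numeric(reg)
    sims[i] <- if (all(vectors[i, ] == 0)) -Inf
               else cosine_similarity(reg, empirical)
  }
  colnames(vectors) <- names(empirical)
  scored <- cbind(pts, similarity = sims)

  pass <- which(sims > threshold)
  if (length(pass) > 0) {
    members <- scored[pass, , drop = FALSE]
    selection_mode <- "threshold"
    diagnostic <- NULL
  } else {
    ord <- order_scored(scored, free)
    members <- scored[ord[seq_len(min(fallback_n, nrow(scored)))], ,
                      drop = FALSE]
    selection_mode <- "best_n"
    diagnostic <- sprintf(
      "no model exceeded similarity %g (best: %.4f); reporting the best %d",
      threshold, max(sims), nrow(members))
  }
  best_i <- order_scored(scored, free)[1]

  fit <- structure(
    list(call = cl, gene_class = gene_class, arch = arch,
         empirical = empirical, threshold = threshold,
         selection_mode = selection_mode, diagnostic = diagnostic,
         free = free, grid = grid, fixed = fixed, protocol = protocol,
         scored = scored, vectors = vectors,
         members = members,
         best = list(rates = modify_rates(fixed,
                                          as.list(scored[best_i, free,
                                                         drop = FALSE])),
                     similarity = sims[best_i],
                     model = region_occupancy(
                       stats::setNames(vectors[best_i, ], names(empirical)),
                       gene_class = gene_class, units = "fraction"))),
    class = "rnapii_fit")
  fit$ranges <- if (nrow(members) > 0) functional_ranges(fit) else NULL
  fit
}

# descending similarity, ties by ascending free rates in canonical order
order_scored <- function(scored, free) {
  do.call(order, c(list(-scored$similarity),
                   lapply(free, function(f) scored[[f]])))
}

#' Per-rate functional ranges of an ensemble
#'
#' The elementwise minimum and maximum of every free rate across the
#' ensemble members -- the range of parameter values consistent with the
#' data at the similarity threshold.
#'
#' @param ensemble An [fit_transcription()] object (or its `members` data
#'   frame together with `free`).
#' @param free Character vector of free-rate names (only needed for a bare
#'   data frame).
#' @return A matrix with rows `min` and `max` and one column per free rate.
#' @export
functional_ranges <- function(ensemble, free = NULL) {
  if (inherits(ensemble, "rnapii_fit")) {
    members <- ensemble$members; free <- ensemble$free
  } else members <- ensemble
  if (is.null(members) || nrow(members) == 0)
    stop("cannot compute functional ranges of an empty ensemble")
  m <- vapply(free, function(f) range(members[[f]]), numeric(2))
  rownames(m) <- c("min", "max")
  m
}

#' Retain the n best-scoring models
#'
#' Replaces the ensemble of a fit by its top `n` grid points by cosine
#' similarity (ties broken by ascending free-rate values in canonical
#' order). This is the reporting mode used when no model passes the
#' threshold.
#'
#' @param fit An [fit_transcription()] object.
#' @param n Number of models to retain.
#' @return The fit with `members` replaced and
#'   `selection_mode = "best_n"`.
#' @export
best_n <- function(fit, n) {
  stopifnot(inherits(fit, "rnapii_fit"))
  if (n < 1) stop("'n' must be >= 1")
  if (n > nrow(fit$scored)) {
    warning(sprintf("only %d candidate models available", nrow(fit$scored)))
    n <- nrow(fit$scored)
  }
  ord <- order_scored(fit$scored, fit$free)
  fit$members <- fit$scored[ord[seq_len(n)], , drop = FALSE]
  fit$selection_mode <- "best_n"
  fit$ranges <- functional_ranges(fit)
  fit
}

#' Serialise a fitted ensemble to JSON
#'
#' @param fit An [fit_transcription()] object.
#' @param file Path to write.
#' @return Invisibly, `file`.
#' @export
write_ensemble <- function(fit, file) {
  stopifnot(inherits(fit, "rnapii_fit"))
  obj <- list(
    gene_class = fit$gene_class,
    threshold = fit$threshold,
    selection_mode = fit$selection_mode,
    seed = fit$protocol$seed,
    n_genes = fit$protocol$n_genes,
    free = fit$free,
    fixed = as.list(fit$fixed$rates[!is.na(fit$fixed$rates)]),
    empirical = as.list(unclass(fit$empirical)),
    members = fit$members,
    ranges = if (!is.null(fit$ranges)) as.data.frame(fit$ranges) else NULL)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}
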