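#' @method print rnapii_fit
#' @export
print.rnapii_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Transcription-cycle fit (%s genes)\n", x$gene_class))
  cat(sprintf("  grid: %d models over %s\n", nrow(x$scored),
              paste(x$free, collapse = ", ")))
  if (x$selection_mode == "threshold")
    cat(sprintf("  ensemble: %d models with cosine similarity > %g\n",
                nrow(x$members), x$threshold))
  else
    cat(sprintf("  ensemble: best %d models (threshold %g not reached)\n",
                nrow(x$members), x$threshold))
  if (!is.null(x$diagnostic)) cat("  note: ", x$diagnostic, "\n", sep = "")
  cat(sprintf("  best similarity: %.4f\n", x$best$similarity))
  if (!is.null(x$ranges)) {
    cat("  functional ranges (/s):\n")
    print(signif(x$ranges, digits))
  }
  invisible(x)
}

#' @method summary rnapii_fit
#' @export
summary.rnapii_fit <- function(object, ...) {
  structure(list(fit = object,
                 n_grid = nrow(object$scored),
                 n_members = nrow(object$members),
                 similarity = stats::quantile(object$scored$similarity,
                                              c(0, 0.5, 0.9, 1))),
            class = "summary.rnapii_fit")
}

#' @method print summary.rnapii_fit
#' @export
print.summary.rnapii_fit <- function(x, ...) {
  print(x$fit)
  cat("  grid similarity quantiles:\n")
  print(signif(x$similarity, 4))
  cat("  best model rates:\n")
  print(x$fit$best$rates)
  invisible(x)
}

#' Best-fit rates of a transcription fit
#'
#' @param object An [fit_transcription()] object.
#' @param ... Unused.
#' @return Named numeric vector of the best-scoring model's defined rates.
#' @method coef rnapii_fit
#' @export
coef.rnapii_fit <- function(object, ...) {
  r <- object$best$rates$rates
  r[!is.na(r)]
}

#' Predicted region occupancy from a fit
#'
#' Re-simulates a rate set (by default the best-scoring ensemble member)
#' under the fit's protocol and returns the region occupancy vector,
#' optionally scaled to the magnitude of the empirical data (see
#' [l2_scale()]).
#'
#' @param object An [fit_transcription()] object.
#' @param rates Optional [rate_set()] to predict for (default: best member).
#' @param scaled If `TRUE` (default) the vector is L2-scaled to the
#'   empirical magnitude.
#' @param protocol Optional [sim_protocol()] override.
#' @param ... Unused.
#' @return A [region_occupancy()] vector.
#' @method predict rnapii_fit
#' @export
predict.rnapii_fit <- function(object, rates = NULL, scaled = TRUE,
                               protocol = NULL, ...) {
  if (is.null(rates) && is.null(protocol)) {
    reg <- object$best$model      # already simulated during the fit
  } else {
    if (is.null(rates)) rates <- object$best$rates
    if (is.null(protocol)) protocol <- object$protocol
    reg <- aggregate_regions(average_occupancy(object$arch, rates, protocol))
  }
  if (scaled) l2_scale(reg, object$empirical) else reg
}

#' @method fitted rnapii_fit
#' @export
fitted.rnapii_fit <- function(object, ...) predict(object, scaled = TRUE)

#' @method residuals rnapii_fit
#' @export
residuals.rnapii_fit <- function(object, ...) {
  r <- unclass(object$empirical) - unclass(fitted(object))
  region_occupancy(stats::setNames(as.numeric(r), names(object$empirical)),
                   gene_class = object$gene_class, units = "delta")
}

#' Simulate region-occupancy replicates from a fitted ensemble
#'
#' Draws `nsim` ensemble members (uniformly, with replacement) and
#' re-simulates each with a fresh master seed, giving replicate region
#' vectors that carry both parameter (ensemble) and Monte-Carlo spread.
#'
#' @param object An [fit_transcription()] object.
#' @param nsim Number of replicates.
#' @param seed Master seed for the replicate streams (default 1).
#' @param ... Unused.
#' @return A matrix with `nsim` rows, one column per region.
#' @method simulate rnapii_fit
#' @export
simulate.rnapii_fit <- function(object, nsim = 1, seed = 1, ...) {
  stopifnot(nsim >= 1)
  set.seed(seed)
  idx <- sample.int(nrow(object$members), nsim, replace = TRUE)
  out <- matrix(NA_real_, nsim, length(object$empirical),
                dimnames = list(NULL, names(object$empirical)))
  for (i in seq_len(nsim)) {
    rs <- modify_rates(object$fixed,
                       as.list(object$members[idx[i], object$free,
                                              drop = FALSE]))
    p <- object$protocol
    p$seed <- p$seed + 1000 * i + seed
    out[i, ] <- as.numeric(aggregate_regions(
      average_occupancy(object$arch, rs, p)))
  }
  out
}

#' Plot a fitted model against the empirical region occupancy
#'
#' Side-by-side bars of the empirical region vector and the (L2-scaled)
#' best-model prediction.
#'
#' @param x An [fit_transcription()] object.
#' @param ... Passed to [graphics::barplot()].
#' @method plot rnapii_fit
#' @export
plot.rnapii_fit <- function(x, ...) {
  emp <- unclass(x$empirical)
  mod <- unclass(fitted(x))
  m <- rbind(empirical = as.numeric(emp), model = as.numeric(mod))
  colnames(m) <- names(x$empirical)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = attr(x$empirical, "units"),
                    main = sprintf("%s fit (cosine similarity %.4f)",
                                   x$gene_class, x$best$similarity), ...)
  invisible(x)
}
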