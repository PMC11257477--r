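#' Define a rate perturbation
#'
#' A hypothesised effect of an experimental treatment on the transcription
#' cycle, expressed as absolute rate overrides (s^-1) and/or multipliers.
#' An empty spec is the explicit identity control.
#'
#' @param label Human-readable label (e.g. `"down k2 + up k_minus1"`).
#' @param override Named list of absolute replacement values.
#' @param multiplier Named list of dimensionless factors applied to the
#'   current value.
#' @return An object of class `"perturbation"`.
#' @examples
#' perturbation("TFIIB depletion (TFO)", override = list(k3 = 0.0008))
#' perturbation("slower initiation", multiplier = list(k5 = 0.2))
#' @export
perturbation <- function(label = NULL, override = list(),
                         multiplier = list()) {
  ok <- names(engine_rate_names())
  bad <- setdiff(c(names(override), names(multiplier)), ok)
  if (length(bad)) stop("unknown rates: ", paste(bad, collapse = ", "))
  if (any(unlist(override) < 0) || any(unlist(multiplier) < 0))
    stop("overrides and multipliers must be nonnegative")
  if (length(intersect(names(override), names(multiplier))))
    stop("a rate cannot have both an override and a multiplier")
  if (is.null(label))
    label <- if (length(override) + length(multiplier) == 0) "identity"
             else paste(c(sprintf("%s=%g", names(override), unlist(override)),
                          sprintf("%sx%g", names(multiplier),
                                  unlist(multiplier))), collapse = ", ")
  structure(list(label = label, override = override,
                 multiplier = multiplier), class = "perturbation")
}

engine_rate_names <- function() {
  stats::setNames(1:10, c("k1", "k_minus1", "k2", "k_minus2", "k3",
                          "k_minus3", "k4", "k5", "k6_speed", "k7"))
}

#' @method print perturbation
#' @export
print.perturbation <- function(x, ...) {
  cat("Perturbation:", x$label, "\n")
  for (nm in names(x$override))
    cat(sprintf("  %s -> %g /s\n", nm, x$override[[nm]]))
  for (nm in names(x$multiplier))
    cat(sprintf("  %s x %g\n", nm, x$multiplier[[nm]]))
  if (!length(x$override) && !length(x$multiplier))
    cat("  (identity control)\n")
  invisible(x)
}

#' Apply a perturbation to a rate set
#'
#' @param rates A [rate_set()].
#' @param spec A [perturbation()]. It may only touch rates defined for the
#'   gene class (e.g. not `k3` for STM genes).
#' @return A modified copy of `rates`; untouched rates are identical.
#' @export
apply_perturbation <- function(rates, spec) {
  stopifnot(inherits(rates, "rate_set"), inherits(spec, "perturbation"))
  r <- rates$rates
  touched <- c(names(spec$override), names(spec$multiplier))
  unset <- touched[is.na(r[touched])]
  if (length(unset))
    stop(sprintf("perturbation touches %s, not defined for %s genes",
                 paste(unset, collapse = ", "), rates$gene_class))
  for (nm in names(spec$override)) r[nm] <- spec$override[[nm]]
  for (nm in names(spec$multiplier)) r[nm] <- r[nm] * spec$multiplier[[nm]]
  out <- rates
  out$rates <- r
  out
}

resolve_members <- function(ensemble) {
  # accept a fitted ensemble or a bare rate_set (singleton ensemble)
  if (inherits(ensemble, "rnapii_fit")) {
    if (nrow(ensemble$members) == 0) stop("empty ensemble")
    lapply(seq_len(nrow(ensemble$members)), function(i)
      modify_rates(ensemble$fixed,
                   as.list(ensemble$members[i, ensemble$free,
                                            drop = FALSE])))
  } else if (inherits(ensemble, "rate_set")) {
    list(ensemble)
  } else stop("'ensemble' must be an rnapii_fit or a rate_set")
}

#' Ensemble-averaged occupancy change under a perturbation
#'
#' For every ensemble member, the baseline and the perturbed rate sets are
#' simulated with paired seeds (the same master seed, hence the same
#' per-gene random substreams), so an identity perturbation gives exactly
#' zero change. Both region vectors are converted to the empirical scale
#' with the single factor `||E|| / ||M_baseline||` derived from the
#' member's baseline vector -- the unit conversion is fixed by the baseline
#' fit, so amplitude changes caused by the perturbation survive. The
#' returned change is `perturbed - baseline`, averaged over members.
#'
#' @param ensemble An [fit_transcription()] object, or a single
#'   [rate_set()] (treated as a one-member ensemble).
#' @param spec A [perturbation()].
#' @param protocol A [sim_protocol()] (default: the fit's, or
#'   `sim_protocol()`).
#' @param empirical Baseline empirical [region_occupancy()] used for the
#'   scale factor (default: the fit's; for a bare rate set the baseline
#'   model vector itself, i.e. scale factor 1).
#' @param arch Gene architecture (default from the gene class).
#' @return An object of class `"delta_occupancy"`: `mean` (signed
#'   per-region change), `se` (across ensemble members; 0 for a singleton),
#'   `n_members`, `label`.
#' @export
ensemble_delta <- function(ensemble, spec, protocol = NULL, empirical = NULL,
                           arch = NULL) {
  members <- resolve_members(ensemble)
  gene_class <- members[[1]]$gene_class
  if (is.null(arch))
    arch <- if (inherits(ensemble, "rnapii_fit")) ensemble$arch
            else gene_architecture(gene_class)
  if (is.null(protocol))
    protocol <- if (inherits(ensemble, "rnapii_fit")) ensemble$protocol
                else sim_protocol()
  if (is.null(empirical) && inherits(ensemble, "rnapii_fit"))
    empirical <- ensemble$empirical

  deltas <- matrix(NA_real_, length(members),
                   if (gene_class == "STM") 4L else 3L)
  for (i in seq_along(members)) {
    base_rates <- members[[i]]
    pert_rates <- apply_perturbation(base_rates, spec)
    base <- aggregate_regions(average_occupancy(arch, base_rates, protocol))
    pert <- aggregate_regions(average_occupancy(arch, pert_rates, protocol))
    sf <- if (is.null(empirical)) 1
          else sqrt(sum(empirical^2)) / sqrt(sum(base^2))
    deltas[i, ] <- sf * (as.numeric(pert) - as.numeric(base))
  }
  regions <- names(aggregate_regions_template(gene_class))
  colnames(deltas) <- regions
  m <- colMeans(deltas)
  se <- if (nrow(deltas) > 1) apply(deltas, 2, stats::sd) / sqrt(nrow(deltas))
        else stats::setNames(numeric(ncol(deltas)), regions)
  structure(list(mean = region_occupancy(m, gene_class = gene_class,
                                         units = "delta"),
                 se = se, n_members = length(members), label = spec$label),
            class = "delta_occupancy")
}

aggregate_regions_template <- function(gene_class) {
  if (gene_class == "STM")
    c(UAS = 0, promoter = 0, transcript = 0, UTR3 = 0)
  else c(promoter = 0, transcript = 0, UTR3 = 0)
}

#' @method print delta_occupancy
#' @export
print.delta_occupancy <- function(x, digits = 4, ...) {
  cat(sprintf("Occupancy change '%s' (%d ensemble member%s)\n", x$label,
              x$n_members, if (x$n_members > 1) "s" else ""))
  print(round(rbind(mean = unclass(x$mean), se = x$se), digits))
  invisible(x)
}

#' Score a model occupancy change against an observed one
#'
#' Cosine similarity on the signed per-region change vectors: 1 for
#' identical direction-and-shape, -1 for an exactly opposite pattern.
#'
#' @param model_delta,empirical_delta `"delta_occupancy"` objects or signed
#'   numeric vectors of matching length.
#' @return Cosine similarity in \[-1, 1\].
#' @export
score_delta <- function(model_delta, empirical_delta) {
  m <- if (inherits(model_delta, "delta_occupancy")) model_delta$mean
       else model_delta
  e <- if (inherits(empirical_delta, "delta_occupancy")) empirical_delta$mean
       else empirical_delta
  cosine_similarity(as.numeric(m), as.numeric(e))
}

#' Rank candidate perturbations against an observed occupancy change
#'
#' Simulates each candidate's ensemble-averaged occupancy change
#' ([ensemble_delta()]) and sorts candidates by [score_delta()] against the
#' observed change, descending (ties by label).
#'
#' @param candidates List of [perturbation()] objects.
#' @param empirical_delta Observed signed change (vector or
#'   `"delta_occupancy"`).
#' @param ensemble An [fit_transcription()] object or [rate_set()].
#' @inheritParams ensemble_delta
#' @return A data frame with columns `label` and `score`, best first; the
#'   simulated changes are attached as `attr(, "deltas")` (a named list).
#' @export
rank_perturbations <- function(candidates, empirical_delta, ensemble,
                               protocol = NULL, empirical = NULL,
                               arch = NULL) {
  if (length(candidates) < 1) stop("need at least one candidate")
  deltas <- lapply(candidates, function(spec)
    ensemble_delta(ensemble, spec, protocol = protocol,
                   empirical = empirical, arch = arch))
  scores <- vapply(deltas, score_delta, numeric(1),
                   empirical_delta = empirical_delta)
  labels <- vapply(candidates, function(s) s$label, character(1))
  ord <- order(-scores, labels)
  out <- data.frame(label = labels[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "deltas") <- stats::setNames(deltas[ord], labels[ord])
  out
}

#' Published perturbation parameter sets
#'
#' The machine-readable table of the modelled chemical-genetic
#' perturbations (TFIIB/Sua7 degradation, TFIIH-kinase/Kin28 inhibition,
#' and the Gcn4 experiments), one row per candidate model. Cells that were
#' published as a re-fitted range are stored as `lo-hi`; exact values have
#' `lo == hi`. The `context` column names the baseline parameter context
#' (`standard` or `gcn4`, which differ in the terminator release rate and
#' the free-rate ranges).
#'
#' @return A data frame (one row per experiment/class/model, rate columns
#'   as character: empty = untouched).
#' @export
perturbation_table <- function() {
  f <- system.file("extdata", "perturbations.tsv", package = "polkin",
                   mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "", colClasses = "character")
}

parse_cell <- function(x) {
  # "lo-hi" -> midpoint (geometric when lo > 0), "v" -> v
  parts <- as.numeric(strsplit(x, "-", fixed = TRUE)[[1]])
  if (length(parts) == 1) return(parts)
  if (parts[1] > 0) sqrt(parts[1] * parts[2]) else mean(parts)
}

#' Build runnable perturbations from the published table
#'
#' `table_perturbation()` returns the single labelled spec; range cells are
#' collapsed to their midpoint (geometric for ranges bounded away from
#' zero). `table_candidates()` returns every model for an experiment/class
#' -- the candidate set that [rank_perturbations()] ranks.
#'
#' @param experiment One of the `experiment` values in
#'   [perturbation_table()] (e.g. `"Sua7 degradation"`,
#'   `"Kin28 inhibition"`, `"gcn4-pd"`, `"gcn4-null"`).
#' @param gene_class `"STM"` or `"TFO"`.
#' @param model Model number within the experiment.
#' @return A [perturbation()] (with a `context` attribute), or a list of
#'   them.
#' @export
table_perturbation <- function(experiment, gene_class, model) {
  tab <- perturbation_table()
  row <- tab[tab$experiment == experiment & tab$gene_class == gene_class &
               tab$model == as.character(model), , drop = FALSE]
  if (nrow(row) != 1)
    stop(sprintf("no table entry for %s / %s / model %s",
                 experiment, gene_class, model))
  rate_cols <- names(engine_rate_names())
  override <- list()
  for (nm in intersect(rate_cols, names(row))) {
    cell <- row[[nm]]
    if (!is.na(cell) && nzchar(cell)) override[[nm]] <- parse_cell(cell)
  }
  spec <- perturbation(sprintf("%s %s model %s", experiment, gene_class,
                               model), override = override)
  attr(spec, "context") <- row$context
  spec
}

#' @rdname table_perturbation
#' @export
table_candidates <- function(experiment, gene_class) {
  tab <- perturbation_table()
  rows <- tab[tab$experiment == experiment & tab$gene_class == gene_class, ,
              drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("no table entries for %s / %s", experiment, gene_class))
  lapply(rows$model, function(m)
    table_perturbation(experiment, gene_class, m))
}
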