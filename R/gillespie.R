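#' Create a gene state
#'
#' The instantaneous configuration of the model gene: whether the UAS holds a
#' polymerase (STM only), the promoter substate (`"EMPTY"`,
#' `"AWAITING_TFIIH"` after early-PIC arrival, `"PIC_COMPLETE"` after TFIIH
#' recruitment), per-bin occupancy flags over the transcribed region, and the
#' terminator flag. At most one polymerase per compartment, always.
#'
#' @param arch A [gene_architecture()].
#' @param uas_occupied Logical; UAS occupancy (STM only).
#' @param promoter_state One of `"EMPTY"`, `"AWAITING_TFIIH"`,
#'   `"PIC_COMPLETE"`.
#' @param transcript_bins Logical vector of length `arch$n_transcript_bins`.
#' @param terminator_occupied Logical.
#' @return An object of class `"gene_state"` with a clock (`time`) and event
#'   tallies (`recruitments`, `initiations`, `completions`).
#' @export
gene_state <- function(arch, uas_occupied = FALSE,
                       promoter_state = "EMPTY",
                       transcript_bins = rep(FALSE, arch$n_transcript_bins),
                       terminator_occupied = FALSE) {
  stopifnot(inherits(arch, "gene_architecture"))
  promoter_state <- match.arg(promoter_state,
                              c("EMPTY", "AWAITING_TFIIH", "PIC_COMPLETE"))
  if (length(transcript_bins) != arch$n_transcript_bins)
    stop("'transcript_bins' must have one flag per transcript bin")
  if (uas_occupied && !arch$has_uas)
    stop("TFO architecture has no UAS compartment")
  structure(
    list(uas_occupied = isTRUE(uas_occupied),
         promoter_state = promoter_state,
         transcript_bins = as.logical(transcript_bins),
         terminator_occupied = isTRUE(terminator_occupied),
         time = 0,
         recruitments = 0L, initiations = 0L, completions = 0L),
    class = "gene_state")
}

#' Enumerate the enabled transitions and their propensities
#'
#' Applies the transition rules of the transcription cycle to a state,
#' honouring the exclusion constraint: a move whose destination compartment
#' is occupied is disabled (propensity zero and omitted), not
#' attempted-and-rejected. Promoter dissociation (`k_minus3`) and reversal to
#' the UAS (`k_minus2`) are only possible while awaiting TFIIH; after PIC
#' completion the only exit is initiation.
#'
#' @param state A [gene_state()].
#' @param rates A [rate_set()] of the matching gene class.
#' @param arch The [gene_architecture()].
#' @return A data frame with columns `transition` (identifier) and
#'   `propensity` (s^-1), one row per enabled transition. Zero-rate
#'   transitions are omitted.
#' @export
enabled_transitions <- function(state, rates, arch) {
  stopifnot(inherits(state, "gene_state"))
  r <- engine_rates(rates, arch)
  names(r) <- c("k1", "k_minus1", "k2", "k_minus2", "k3", "k_minus3",
                "k4", "k5", "hop", "k7")
  bins <- state$transcript_bins
  n <- arch$n_transcript_bins
  id <- character(0); p <- numeric(0)
  add <- function(nm, rate) {
    if (rate > 0) { id <<- c(id, nm); p <<- c(p, rate) }
  }
  if (arch$has_uas) {
    if (!state$uas_occupied) add("recruit_uas", r[["k1"]])
    if (state$uas_occupied) add("uas_loss", r[["k_minus1"]])
    if (state$uas_occupied && state$promoter_state == "EMPTY")
      add("transfer", r[["k2"]])
    if (state$promoter_state == "AWAITING_TFIIH" && !state$uas_occupied)
      add("reversal", r[["k_minus2"]])
  }
  if (state$promoter_state == "EMPTY") add("recruit_promoter", r[["k3"]])
  if (state$promoter_state == "AWAITING_TFIIH") {
    add("promoter_loss", r[["k_minus3"]])
    add("tfiih", r[["k4"]])
  }
  if (state$promoter_state == "PIC_COMPLETE" && !bins[1])
    add("initiate", r[["k5"]])
  if (n > 1) {
    for (i in seq_len(n - 1))
      if (bins[i] && !bins[i + 1]) add(paste0("hop_", i), r[["hop"]])
  }
  if (bins[n] && !state$terminator_occupied) add("enter_terminator", r[["hop"]])
  if (state$terminator_occupied) add("release", r[["k7"]])
  data.frame(transition = id, propensity = unname(p),
             stringsAsFactors = FALSE)
}

apply_transition <- function(state, transition) {
  s <- state
  if (transition == "recruit_uas") {
    s$uas_occupied <- TRUE; s$recruitments <- s$recruitments + 1L
  } else if (transition == "uas_loss") {
    s$uas_occupied <- FALSE
  } else if (transition == "transfer") {
    s$uas_occupied <- FALSE; s$promoter_state <- "AWAITING_TFIIH"
  } else if (transition == "reversal") {
    s$promoter_state <- "EMPTY"; s$uas_occupied <- TRUE
  } else if (transition == "recruit_promoter") {
    s$promoter_state <- "AWAITING_TFIIH"; s$recruitments <- s$recruitments + 1L
  } else if (transition == "promoter_loss") {
    s$promoter_state <- "EMPTY"
  } else if (transition == "tfiih") {
    s$promoter_state <- "PIC_COMPLETE"
  } else if (transition == "initiate") {
    s$promoter_state <- "EMPTY"; s$transcript_bins[1] <- TRUE
    s$initiations <- s$initiations + 1L
  } else if (transition == "enter_terminator") {
    s$transcript_bins[length(s$transcript_bins)] <- FALSE
    s$terminator_occupied <- TRUE
  } else if (transition == "release") {
    s$terminator_occupied <- FALSE; s$completions <- s$completions + 1L
  } else if (grepl("^hop_", transition)) {
    i <- as.integer(sub("^hop_", "", transition))
    s$transcript_bins[i] <- FALSE
    s$transcript_bins[i + 1] <- TRUE
  } else stop("unknown transition: ", transition)
  s
}

#' Advance the gene state by one Gillespie event
#'
#' Draws an exponential waiting time with rate equal to the total propensity
#' and picks the transition with probability proportional to its propensity,
#' using R's RNG (seed with [set.seed()] for reproducibility). If no
#' transition is enabled the state is absorbed: the waiting time is `Inf`
#' and the state is returned unchanged.
#'
#' @inheritParams enabled_transitions
#' @return A list with `transition` (character, or `NA` when absorbed),
#'   `waiting_time` (s) and `state` (the updated [gene_state()], its clock
#'   advanced).
#' @export
gillespie_step <- function(state, rates, arch) {
  en <- enabled_transitions(state, rates, arch)
  if (nrow(en) == 0)
    return(list(transition = NA_character_, waiting_time = Inf, state = state))
  total <- sum(en$propensity)
  tau <- stats::rexp(1, rate = total)
  i <- if (nrow(en) == 1) 1L
       else sample.int(nrow(en), 1L, prob = en$propensity)
  s <- apply_transition(state, en$transition[i])
  s$time <- state$time + tau
  list(transition = en$transition[i], waiting_time = tau, state = s)
}

#' Simulate one gene through the transcription cycle (reference engine)
#'
#' Pure-R Gillespie simulation of one gene, starting empty, for
#' `total_time` seconds; time-weighted compartment occupancy is recorded
#' over the final `record_window` seconds (both promoter substates count as
#' promoter occupancy). Intervals straddling the window boundary are split
#' exactly. This is the readable reference implementation; ensemble-scale
#' runs use the compiled engine behind [average_occupancy()].
#'
#' @inheritParams enabled_transitions
#' @param total_time Simulated time in s (default 1000, enough burn-in to
#'   reach steady state).
#' @param record_window Recording window in s at the end of the run
#'   (default 60, matching the cleavage-reaction timescale).
#' @param keep_events If `TRUE`, also return the full event log (time,
#'   transition) for invariant checking.
#' @return An object of class `"gene_trace"`: `occupancy` (named
#'   per-compartment fractions in \[0,1\]), `events` (tallies), `interval`
#'   (recorded window), `final_state`, and optionally `log`.
#' @export
simulate_gene <- function(arch, rates, total_time = 1000, record_window = 60,
                          keep_events = FALSE) {
  if (record_window > total_time)
    stop("'record_window' must not exceed 'total_time'")
  state <- gene_state(arch)
  comp <- compartment_names(arch)
  occ <- stats::setNames(numeric(length(comp)), comp)
  rec_start <- total_time - record_window
  log_t <- numeric(0); log_e <- character(0)

  occupied_vec <- function(s) {
    c(if (arch$has_uas) s$uas_occupied,
      s$promoter_state != "EMPTY",
      s$transcript_bins, s$terminator_occupied)
  }
  t <- 0
  repeat {
    step <- gillespie_step(state, rates, arch)
    t_next <- min(t + step$waiting_time, total_time)
    a <- max(t, rec_start)
    if (t_next > a) occ <- occ + occupied_vec(state) * (t_next - a)
    if (is.infinite(step$waiting_time) || t + step$waiting_time >= total_time)
      break
    if (keep_events) {
      log_t <- c(log_t, t_next); log_e <- c(log_e, step$transition)
    }
    state <- step$state
    t <- t_next
  }
  out <- list(occupancy = occ / record_window,
              events = c(recruitments = state$recruitments,
                         initiations = state$initiations,
                         completions = state$completions),
              interval = c(start = rec_start, end = total_time),
              final_state = state)
  if (keep_events)
    out$log <- data.frame(time = log_t, transition = log_e,
                          stringsAsFactors = FALSE)
  structure(out, class = "gene_trace")
}

#' @method print gene_trace
#' @export
print.gene_trace <- function(x, ...) {
  cat(sprintf("Gene trace: occupancy over [%g, %g] s\n",
              x$interval[1], x$interval[2]))
  print(round(x$occupancy, 4))
  cat(sprintf("events: %d recruitments, %d initiations, %d completions\n",
              x$events[["recruitments"]], x$events[["initiations"]],
              x$events[["completions"]]))
  invisible(x)
}
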