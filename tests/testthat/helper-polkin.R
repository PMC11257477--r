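# shared fixtures: small, fast defaults for unit tests

quick_protocol <- function(n_genes = 500, seed = 1)
  sim_protocol(total_time = 1000, record_window = 60,
               n_genes = n_genes, seed = seed)

# a TFO rate set with every downstream step active (used where speed matters
# more than realism: higher recruitment gives better-conditioned occupancy)
busy_tfo <- function()
  rate_set("TFO", k3 = 0.01, k_minus3 = 0.01, k4 = 0.05,
           k5 = 0.1, k6_speed = 1000, k7 = 0.037)

# replay an event log against the transition rules, asserting exclusion and
# irreversibility at every step; returns the final state
replay_log <- function(log, arch) {
  state <- gene_state(arch)
  n <- arch$n_transcript_bins
  for (ev in log$transition) {
    if (ev == "initiate")
      stopifnot(!state$transcript_bins[1],
                state$promoter_state == "PIC_COMPLETE")
    if (grepl("^hop_", ev)) {
      i <- as.integer(sub("^hop_", "", ev))
      stopifnot(state$transcript_bins[i], !state$transcript_bins[i + 1])
    }
    if (ev == "enter_terminator")
      stopifnot(state$transcript_bins[n], !state$terminator_occupied)
    if (ev == "tfiih") stopifnot(state$promoter_state == "AWAITING_TFIIH")
    if (ev %in% c("promoter_loss", "reversal"))
      stopifnot(state$promoter_state == "AWAITING_TFIIH")
    state <- polkin:::apply_transition(state, ev)
    stopifnot(sum(state$transcript_bins) <= n)
  }
  state
}
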