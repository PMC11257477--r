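test_that("enabled transitions follow the cycle rules and exclusion", {
  tfo <- gene_architecture("TFO")
  r <- default_rates("TFO")
  en <- enabled_transitions(gene_state(tfo), r, tfo)
  expect_equal(en$transition, "recruit_promoter")
  expect_equal(en$propensity, unname(r["k3"]))

  stm <- gene_architecture("STM")
  rs <- default_rates("STM")
  s <- gene_state(stm, uas_occupied = TRUE)
  en2 <- enabled_transitions(s, rs, stm)
  expect_setequal(en2$transition, c("uas_loss", "transfer"))

  # occupied promoter blocks the transfer but enables reversal only when
  # the UAS is free
  s3 <- gene_state(stm, uas_occupied = TRUE,
                   promoter_state = "AWAITING_TFIIH")
  en3 <- enabled_transitions(s3, rs, stm)
  expect_false("transfer" %in% en3$transition)
  expect_false("reversal" %in% en3$transition)
  s4 <- gene_state(stm, promoter_state = "AWAITING_TFIIH")
  expect_true("reversal" %in% enabled_transitions(s4, rs, stm)$transition)

  # after PIC completion the only exit is initiation, blocked by bin 1
  s5 <- gene_state(stm, promoter_state = "PIC_COMPLETE",
                   transcript_bins = c(TRUE, rep(FALSE, 9)))
  en5 <- enabled_transitions(s5, rs, stm)
  expect_false(any(c("initiate", "promoter_loss", "reversal") %in%
                     en5$transition))

  zero <- rate_set("TFO", k3 = 0, k_minus3 = 0, k4 = 0, k5 = 0,
                   k6_speed = NA, k7 = 0)
  expect_equal(nrow(enabled_transitions(gene_state(tfo), zero, tfo)), 0)

  expect_error(gene_state(tfo, uas_occupied = TRUE), "no UAS")
})

test_that("gillespie steps obey the waiting-time and selection laws", {
  tfo <- gene_architecture("TFO")
  r <- rate_set("TFO", k3 = 0.002, k5 = 0.1, k6_speed = 1000, k7 = 0.037)
  s <- gene_state(tfo)
  set.seed(42)
  # single enabled transition: always chosen; mean waiting time 1/k3
  n <- 1e4
  waits <- replicate(n, gillespie_step(s, r, tfo)$waiting_time)
  expect_equal(mean(waits), 500, tolerance = 3 / sqrt(n))
  step <- gillespie_step(s, r, tfo)
  expect_equal(step$transition, "recruit_promoter")
  expect_equal(step$state$promoter_state, "AWAITING_TFIIH")

  # two equal propensities: each chosen ~50%
  req <- rate_set("TFO", k3 = 0.002, k_minus3 = 0.05, k4 = 0.05,
                  k5 = 0.1, k6_speed = 1000, k7 = 0.037)
  s2 <- gene_state(tfo, promoter_state = "AWAITING_TFIIH")
  set.seed(7)
  picks <- replicate(4000, gillespie_step(s2, req, tfo)$transition)
  frac <- mean(picks == "tfiih")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))

  # absorbed state: sentinel with infinite waiting time
  zero <- rate_set("TFO", k3 = 0, k_minus3 = 0, k4 = 0, k5 = 0,
                   k6_speed = NA, k7 = 0)
  stepz <- gillespie_step(gene_state(tfo), zero, tfo)
  expect_true(is.infinite(stepz$waiting_time))
  expect_true(is.na(stepz$transition))
})

test_that("single-gene traces respect conservation, exclusion and bounds", {
  tfo <- gene_architecture("TFO")
  r <- busy_tfo()
  set.seed(11)
  tr <- simulate_gene(tfo, r, total_time = 600, record_window = 100,
                      keep_events = TRUE)
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
  expect_lte(tr$events[["completions"]], tr$events[["initiations"]])
  # conservation: polymerases in = polymerases out + polymerases on gene
  fs <- tr$final_state
  on_gene <- sum(fs$transcript_bins) + fs$terminator_occupied
  expect_equal(tr$events[["initiations"]] - tr$events[["completions"]],
               on_gene)
  # replay the event log: exclusion and irreversibility hold at every event
  final <- replay_log(tr$log, tfo)
  expect_equal(sum(final$transcript_bins), sum(fs$transcript_bins))

  # zero recruitment: nothing ever happens
  quiet <- rate_set("TFO", k3 = 0, k_minus3 = 0, k4 = 0.05, k5 = 0.1,
                    k6_speed = 1000, k7 = 0.037)
  tr0 <- simulate_gene(tfo, quiet, total_time = 200, record_window = 50)
  expect_true(all(tr0$occupancy == 0))
  expect_true(all(tr0$events == 0))

  # fixed seed: bit-identical traces
  set.seed(99); a <- simulate_gene(tfo, r, 300, 60, keep_events = TRUE)
  set.seed(99); b <- simulate_gene(tfo, r, 300, 60, keep_events = TRUE)
  expect_identical(a, b)

  expect_error(simulate_gene(tfo, r, total_time = 50, record_window = 60),
               "must not exceed")
})

test_that("an absorbing terminator captures all polymerase", {
  tfo <- gene_architecture("TFO", n_transcript_bins = 3)
  r <- rate_set("TFO", k3 = 0.05, k_minus3 = 0, k4 = 0.2, k5 = 0.2,
                k6_speed = 2000, k7 = 0)
  set.seed(5)
  tr <- simulate_gene(tfo, r, total_time = 3000, record_window = 60)
  expect_gt(tr$occupancy[["UTR3"]], 0.999)
})
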