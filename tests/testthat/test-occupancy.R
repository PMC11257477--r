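test_that("ensemble occupancy is deterministic, bounded and zero without input", {
  tfo <- gene_architecture("TFO")
  p <- quick_protocol(n_genes = 300, seed = 4)
  occ <- average_occupancy(tfo, busy_tfo(), p)
  expect_true(all(occ$mean >= 0 & occ$mean <= 1))
  expect_true(all(occ$se >= 0))
  expect_identical(occ, average_occupancy(tfo, busy_tfo(), p))

  quiet <- rate_set("TFO", k3 = 0, k_minus3 = 0, k4 = 0.05, k5 = 0.1,
                    k6_speed = 1000, k7 = 0.037)
  occ0 <- average_occupancy(tfo, quiet, p)
  expect_true(all(occ0$mean == 0))
})

test_that("region aggregation averages transcript bins and keeps the class", {
  v <- c(UAS = 0.02, promoter = 0.05,
         stats::setNames(rep(0.04, 10), paste0("bin", 1:10)), UTR3 = 0.03)
  reg <- aggregate_regions(v)
  expect_s3_class(reg, "region_occupancy")
  expect_length(reg, 4)
  expect_equal(unname(reg["transcript"]), 0.04)

  v2 <- c(promoter = 0.05,
          stats::setNames(c(0.1, rep(0, 9)), paste0("bin", 1:10)),
          UTR3 = 0.03)
  reg2 <- aggregate_regions(v2)
  expect_length(reg2, 3)
  expect_equal(unname(reg2["transcript"]), 0.01)
  expect_equal(attr(reg2, "gene_class"), "TFO")
})

test_that("L2 scaling matches magnitudes and preserves cosine similarity", {
  expect_equal(l2_scale(c(3, 4), c(5, 0)), c(3, 4))
  expect_equal(l2_scale(c(1, 1), c(2, 2)), c(2, 2))
  expect_equal(l2_scale(c(1, 2, 2), c(2, 4, 4)), c(2, 4, 4))
  x <- l2_scale(c(1, 2, 2), c(6, 0, 0))
  expect_equal(x, c(2, 4, 4))
  expect_error(l2_scale(c(0, 0), c(1, 1)), "all-zero")
  expect_error(l2_scale(c(1, 2), c(1, 2, 3)), "equal length")

  model <- region_occupancy(c(promoter = 0.05, transcript = 0.01,
                              UTR3 = 0.03), units = "fraction")
  emp <- region_occupancy(c(promoter = 40, transcript = 9, UTR3 = 22),
                          units = "CPMn")
  scaled <- l2_scale(model, emp)
  expect_equal(sqrt(sum(scaled^2)), sqrt(sum(emp^2)), tolerance = 1e-12)
  expect_equal(attr(scaled, "scaling"), "l2_scaled")
  expect_equal(cosine_similarity(scaled, emp), cosine_similarity(model, emp))
})

test_that("the exact stationary solver reproduces closed forms", {
  # two-state toy: promoter on/off with k3, k_minus3 only
  tfo <- gene_architecture("TFO", n_transcript_bins = 2)
  r <- rate_set("TFO", k3 = 0.002, k_minus3 = 0.01)
  an <- analytic_steady_state(tfo, r)
  expect_equal(an$mean[["promoter"]], 0.002 / 0.012, tolerance = 1e-9)
  expect_true(all(an$se == 0))

  quiet <- rate_set("TFO", k3 = 0, k_minus3 = 0, k4 = 0.05, k5 = 0.1,
                    k6_speed = 1000, k7 = 0.037)
  an0 <- analytic_steady_state(tfo, quiet)
  expect_true(all(an0$mean == 0))

  # absorbing chain (k7 = 0 with inflow) is flagged and fully loaded
  absb <- rate_set("TFO", k3 = 0.05, k_minus3 = 0, k4 = 0.2, k5 = 0.2,
                   k6_speed = 2000, k7 = 0)
  ana <- analytic_steady_state(tfo, absb)
  expect_true(attr(ana, "absorbing"))
  expect_gt(ana$mean[["UTR3"]], 0.999)
})

test_that("Gillespie and exact occupancies agree on a reduced gene", {
  tfo <- gene_architecture("TFO", n_transcript_bins = 3)
  r <- busy_tfo()
  an <- analytic_steady_state(tfo, r)
  occ <- average_occupancy(tfo, r, quick_protocol(n_genes = 2000, seed = 13))
  z <- abs(occ$mean - an$mean) / pmax(occ$se, 1e-12)
  expect_lt(max(z), 3)
  # throughput identity: completion rate = k7 x terminator occupancy
  expect_equal(an$completion_rate, 0.037 * an$mean[["UTR3"]],
               tolerance = 1e-9)
  expect_lt(abs(occ$completion_rate - an$completion_rate),
            3 * 0.037 * occ$se[["UTR3"]] + 3 * an$completion_rate / sqrt(2000))
})

test_that("occupancy responds monotonically to dissociation and recruitment", {
  tfo <- gene_architecture("TFO")
  p <- quick_protocol(n_genes = 2000, seed = 8)
  lo <- average_occupancy(tfo, rate_set("TFO", k3 = 0.002, k_minus3 = 0,
                                        k4 = 0.03, k5 = 0.1,
                                        k6_speed = 1000, k7 = 0.037), p)
  hi <- average_occupancy(tfo, rate_set("TFO", k3 = 0.002, k_minus3 = 0.03,
                                        k4 = 0.03, k5 = 0.1,
                                        k6_speed = 1000, k7 = 0.037), p)
  expect_gte(lo$mean[["promoter"]], hi$mean[["promoter"]])

  stm <- gene_architecture("STM")
  base <- default_rates("STM")
  lo1 <- average_occupancy(stm, polkin:::modify_rates(base, list(k1 = 0.001)), p)
  hi1 <- average_occupancy(stm, polkin:::modify_rates(base, list(k1 = 0.004)), p)
  expect_gte(hi1$mean[["UAS"]], lo1$mean[["UAS"]])
})

test_that("region vectors survive the text round trip", {
  reg <- region_occupancy(c(UAS = 12.5, promoter = 40.25, transcript = 9,
                            UTR3 = 22), units = "CPMn")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_occupancy(reg, f, se = c(1, 2, 0.5, 1.5))
  back <- read_region_occupancy(f)
  expect_equal(as.numeric(back), as.numeric(reg))
  expect_equal(names(back), names(reg))
  expect_equal(unname(attr(back, "se")), c(1, 2, 0.5, 1.5))
})
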