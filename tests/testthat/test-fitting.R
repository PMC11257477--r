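test_that("cosine similarity matches hand-computed values and invariances", {
  expect_equal(cosine_similarity(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  x <- c(0.3, 1.2, 0.05, 0.7)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(17.3 * x, c(1, 0, 2, 5)),
               cosine_similarity(x, c(1, 0, 2, 5)))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "all-zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("grid specifications validate and generate the stated spacings", {
  expect_error(grid_spec(-1, 2), "lower")
  expect_error(grid_spec(0, 1, spacing = "log"), "log spacing")
  expect_error(grid_spec(0.1, 1, n = 1), ">= 2 points")
  lin <- polkin:::grid_values(grid_spec(0, 0.15, 4, "linear"))
  expect_equal(lin, c(0, 0.05, 0.10, 0.15))
  lg <- polkin:::grid_values(grid_spec(0.03, 0.2, 5, "log"))
  expect_equal(lg[1], 0.03)
  expect_equal(lg[5], 0.2)
  expect_equal(diff(log(lg)), rep(diff(log(c(0.03, 0.2))) / 4, 4))
  expect_equal(polkin:::grid_values(grid_spec(0.1, 0.1)), 0.1)
  g <- default_grid("STM", 6)
  expect_setequal(names(g), c("k2", "k_minus2", "k_minus3", "k4"))
  expect_equal(g$k2$spacing, "log")
  expect_equal(g$k_minus3$spacing, "linear")
})

test_that("a noise-free self-fit recovers the generating grid point", {
  proto <- quick_protocol(n_genes = 2000, seed = 31)
  grid <- default_grid("TFO", points_per_dim = 3)
  pts <- expand.grid(lapply(grid, polkin:::grid_values))
  truth <- polkin:::modify_rates(default_rates("TFO"), as.list(pts[14, ]))
  emp <- synth_empirical_occupancy(truth, noise = noise_model(sigma = 0),
                                   protocol = proto)
  fit <- fit_transcription(emp, "TFO", grid = grid, protocol = proto)
  expect_equal(fit$selection_mode, "threshold")
  # common random numbers: the generating point scores exactly 1
  expect_gte(fit$best$similarity, 0.999)
  expect_equal(unname(coef(fit)["k3"]), pts[14, "k3"])
  expect_equal(unname(coef(fit)["k4"]), pts[14, "k4"])
  in_range <- function(nm) {
    pts[14, nm] >= fit$ranges["min", nm] & pts[14, nm] <= fit$ranges["max", nm]
  }
  expect_true(all(vapply(fit$free, in_range, logical(1))))

  # 1-point grid equal to the truth: ensemble of exactly one model
  g1 <- lapply(as.list(pts[14, ]), function(v) grid_spec(v, v))
  fit1 <- fit_transcription(emp, "TFO", grid = g1, protocol = proto)
  expect_equal(nrow(fit1$members), 1)
  expect_equal(unname(unlist(fit1$members[1, fit1$free])),
               unname(unlist(pts[14, fit1$free])))
})

test_that("ensembles shrink with the threshold and ranges bracket the best", {
  proto <- quick_protocol(n_genes = 400, seed = 17)
  truth <- default_rates("TFO")
  emp <- synth_empirical_occupancy(truth, noise = noise_model(sigma = 0.05,
                                                              seed = 2),
                                   protocol = proto)
  fit <- fit_transcription(emp, "TFO",
                           grid = default_grid("TFO", points_per_dim = 4),
                           protocol = proto)
  n995 <- sum(fit$scored$similarity > 0.995)
  n999 <- sum(fit$scored$similarity > 0.999)
  expect_lte(n999, n995)
  expect_equal(nrow(fit$members), n995)
  for (nm in fit$free) {
    best_val <- fit$scored[which.max(fit$scored$similarity), nm]
    expect_gte(best_val, fit$ranges["min", nm])
    expect_lte(best_val, fit$ranges["max", nm])
  }
})

test_that("an unreachable threshold falls back to best-n reporting", {
  proto <- quick_protocol(n_genes = 300, seed = 23)
  # transcript-dominated shape (crosslinking-like): the model cannot match it
  emp <- region_occupancy(c(promoter = 2, transcript = 100, UTR3 = 5),
                          units = "CPMn")
  fit <- fit_transcription(emp, "TFO",
                           grid = default_grid("TFO", points_per_dim = 3),
                           protocol = proto, fallback_n = 10)
  expect_equal(fit$selection_mode, "best_n")
  expect_equal(nrow(fit$members), 10)
  expect_match(fit$diagnostic, "no model exceeded")
  expect_error(functional_ranges(fit$members[0, ], fit$free), "empty")
})

test_that("best-n selection orders by similarity with lexicographic ties", {
  scored <- data.frame(k3 = c(0.002, 0.001, 0.003, 0.001),
                       k4 = c(0.05, 0.09, 0.01, 0.02),
                       similarity = c(0.9, 0.99, 0.99, 0.99))
  ord <- polkin:::order_scored(scored, c("k3", "k4"))
  expect_equal(ord, c(4, 2, 3, 1))  # ties at 0.99: ascending k3 then k4

  proto <- quick_protocol(n_genes = 200, seed = 29)
  emp <- synth_empirical_occupancy(default_rates("TFO"),
                                   noise = noise_model(sigma = 0.05),
                                   protocol = proto)
  fit <- fit_transcription(emp, "TFO",
                           grid = default_grid("TFO", points_per_dim = 3),
                           protocol = proto)
  top1 <- best_n(fit, 1)
  expect_equal(top1$members$similarity, max(fit$scored$similarity))
  expect_warning(best_n(fit, 1000), "available")
})

test_that("fit objects expose the standard modelling interface", {
  proto <- quick_protocol(n_genes = 300, seed = 37)
  emp <- synth_empirical_occupancy(default_rates("TFO"),
                                   noise = noise_model(sigma = 0.05),
                                   protocol = proto)
  fit <- fit_transcription(emp, "TFO",
                           grid = default_grid("TFO", points_per_dim = 3),
                           protocol = proto)
  expect_output(print(fit), "ensemble")
  expect_output(print(summary(fit)), "similarity quantiles")
  co <- coef(fit)
  expect_true(all(c("k3", "k_minus3", "k4", "k5", "k7") %in% names(co)))
  pr <- predict(fit)
  expect_s3_class(pr, "region_occupancy")
  expect_equal(sqrt(sum(pr^2)), sqrt(sum(emp^2)), tolerance = 1e-10)
  expect_equal(as.numeric(residuals(fit)),
               as.numeric(emp) - as.numeric(fitted(fit)))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(dim(sims), c(2, 3))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble(fit, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$gene_class, "TFO")
  expect_equal(length(obj$members$similarity), nrow(fit$members))
})
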