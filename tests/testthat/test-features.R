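test_that("normalized rank maps winners to 0 and last place to 1", {
  expect_equal(normalized_rank(0, 7), 0)
  expect_equal(normalized_rank(6, 7), 1)
  expect_equal(normalized_rank(1, 3), 0.5)
  expect_equal(normalized_rank(0:4, 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(normalized_rank(0, 1), ">= 2")
  expect_error(normalized_rank(3, 3), "\\[0, n_players - 1\\]")
})

test_that("the median normalized rank summarizes repeated entries", {
  expect_equal(median_normalized_rank(c(0, 0, 0)), 0)
  expect_equal(median_normalized_rank(c(0, 0.5, 1)), 0.5)
  expect_error(median_normalized_rank(numeric(0)), "empty")
})

test_that("cooperation aggregates and ratios are internally consistent", {
  flat <- cooperation_aggregates(rep(0.6, 4))
  expect_true(all(flat$C_r_over_C_max == 1))
  expect_true(all(flat$C_min_over_C_r == 1))
  expect_true(all(flat$C_r_over_C_mean == 1))
  expect_true(all(flat$C_r_over_C_median == 1))

  mixed <- cooperation_aggregates(c(0, 0.5, 1))
  expect_equal(mixed$C_max[1], 1)
  expect_equal(mixed$C_min[1], 0)
  expect_equal(mixed$C_mean[1], 0.5)
  expect_true(is.na(mixed$C_min_over_C_r[1]))  # C_r = 0 denominator

  set.seed(41)
  for (i in 1:10) {
    agg <- cooperation_aggregates(runif(sample(3:30, 1)))
    expect_lte(agg$C_min[1], agg$C_mean[1])
    expect_lte(agg$C_min[1], agg$C_median[1])
    expect_gte(agg$C_max[1], agg$C_mean[1])
    expect_gte(agg$C_max[1], agg$C_median[1])
  }
})

test_that("memory usage is the memory size over the match length, capped", {
  expect_equal(memory_usage(2, 100), 0.02)
  expect_equal(memory_usage(Inf, 100), 1)
  expect_equal(memory_usage(5, 2), 1)
  expect_equal(memory_usage(0, 10), 0)
  expect_true(is.na(memory_usage(2, NA)))
  expect_equal(memory_usage(c(1, Inf, 300), 200), c(0.005, 1, 1))
})

test_that("exact ZD vectors project with zero SSE and recovered parameters", {
  fit <- sse_to_zd(zd_vector(0.1, 2))
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  expect_equal(fit$phi, 0.1, tolerance = 1e-6)
  expect_equal(fit$chi, 2, tolerance = 1e-6)

  tft <- sse_to_zd(c(1, 0, 1, 0))
  expect_equal(tft$sse, 0, tolerance = 1e-12)
  expect_equal(tft$a, 0.2, tolerance = 1e-9)
  expect_equal(tft$b, 0.2, tolerance = 1e-9)

  coop <- sse_to_zd(c(1, 1, 1, 1))
  expect_gte(coop$sse, 1)

  set.seed(42)
  for (i in 1:20) {
    chi <- runif(1, 1, 5)
    phi_max <- min(1 / (1 + 4 * chi), 1 / (4 + chi),
                   if (chi > 1) 1 / (2 * chi - 2) else Inf)
    phi <- runif(1, 0.2, 0.9) * phi_max
    fit <- sse_to_zd(zd_vector(phi, chi))
    expect_lt(fit$sse, 1e-12)
    expect_equal(fit$phi, phi, tolerance = 1e-6)
    expect_equal(fit$chi, chi, tolerance = 1e-6)
  }
})

test_that("the analytic SSE fit agrees with an exhaustive grid search", {
  set.seed(43)
  for (i in 1:100) {
    p <- runif(4)
    fit <- sse_to_zd(p)
    oracle <- grid_sse(p)
    expect_lt(abs(fit$sse - oracle$sse), 1e-4)
  }
})

test_that("the constrained fit clamps to the extortionate cone", {
  # Unconditional cooperation pushes the unconstrained optimum to
  # negative coefficients in one coordinate for some vectors.
  p <- c(0.2, 0.9, 0.05, 0.9)
  con <- sse_to_zd(p)
  unc <- sse_to_zd(p, constrained = FALSE)
  expect_gte(con$a, 0)
  expect_gte(con$b, 0)
  expect_lte(unc$sse, con$sse + 1e-12)
  oracle <- grid_sse(p)
  expect_lt(abs(con$sse - oracle$sse), 1e-4)
})

test_that("zd fits expose tidy and glance views", {
  fit <- sse_to_zd(c(8 / 9, 1 / 2, 1 / 3, 0))
  td <- tidy(fit)
  expect_equal(td$state, c("CC", "CD", "DC", "DD"))
  expect_equal(td$p_tilde, c(-1 / 9, -1 / 2, 1 / 3, 0))
  expect_equal(td$residual, rep(0, 4), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$chi, 2, tolerance = 1e-9)
  expect_equal(gl$sse_clipped, 0, tolerance = 1e-12)
})

test_that("feature rows derive correctly from a tournament summary", {
  s <- run_tournament(c("Cooperator", "Defector", "Tit For Tat",
                        "Grudger"), n = 10, k = 2, seed = 2)
  f <- summary_features(s, trial_id = 7L)
  expect_equal(names(f), ipdsim:::feature_columns())
  expect_equal(nrow(f), 4L)
  expect_equal(f$trial, rep(7L, 4))
  expect_equal(f$tournament_type, rep("standard", 4))
  expect_true(all(f$normalized_rank >= 0 & f$normalized_rank <= 1))
  expect_equal(f$normalized_rank[f$rank == 0L], 0)
  expect_equal(f$normalized_rank, f$rank / 3)
  expect_equal(f$n, rep(10L, 4))
  expect_true(all(is.na(f$p_e)))
  expect_equal(f$memory_usage[f$name == "Grudger"], 1)
  expect_equal(f$memory_usage[f$name == "Tit For Tat"], 0.1)
  expect_true(all(f$SSE >= 0))
  # every strategy here misses at least one joint state against this
  # field, so the SSE imputation flag must be visible somewhere
  expect_type(f$sse_imputed, "logical")

  pe <- run_tournament(c("Cooperator", "Defector", "Tit For Tat"),
                       p_e = 0.3, k = 2, seed = 3)
  fpe <- summary_features(pe)
  expect_true(all(is.na(fpe$memory_usage)))
  expect_true(all(is.na(fpe$n)))
  expect_equal(fpe$p_e, rep(0.3, 3))
})
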