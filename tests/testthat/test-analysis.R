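test_that("correlations recover perfect monotone relationships", {
  tab <- generate_feature_table(synthetic_spec(n_tournaments = 10,
                                               types = "standard",
                                               seed = 1))
  tab$monotone_up <- tab$normalized_rank
  tab$monotone_down <- -tab$normalized_rank
  out <- correlate_features(tab, targets = "normalized_rank",
                            feature_cols = c("monotone_up",
                                             "monotone_down", "SSE"))
  up <- out$estimate[out$feature == "monotone_up"]
  down <- out$estimate[out$feature == "monotone_down"]
  expect_equal(up, 1)
  expect_equal(down, -1)
})

test_that("spearman matches a rank-then-pearson brute force", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    # discrete draws force ties; sprinkle missing values
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- 0.4 * x + sample(1:5, n, replace = TRUE)
    x[sample(n, 2)] <- NA
    tab <- tibble::tibble(tournament_type = "standard",
                          normalized_rank = y, feat = x)
    est <- correlate_features(tab, targets = "normalized_rank",
                              feature_cols = "feat")$estimate
    expect_equal(est, brute_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("constant or unavailable features yield no correlation row", {
  tab <- generate_feature_table(synthetic_spec(
    n_tournaments = 5, types = "probabilistic_ending", seed = 2))
  out <- correlate_features(tab, targets = "normalized_rank",
                            feature_cols = c("SSE", "memory_usage",
                                             "p_n"))
  expect_true("SSE" %in% out$feature)
  expect_false("memory_usage" %in% out$feature)  # undefined without n
  expect_false("p_n" %in% out$feature)           # constant at 0
})

test_that("a noiseless planted model is recovered exactly", {
  # every planted feature sits in the default design of all four types,
  # so with sigma = 0 ordinary least squares interpolates the response
  spec <- synthetic_spec(n_tournaments = 30, sigma = 0,
                         betas = c(CD_to_C = 0.15, SSE = 0.12,
                                   CC_to_C = -0.12,
                                   C_r_over_C_mean = -0.10),
                         seed = 3)
  tab <- generate_feature_table(spec)
  fit <- fit_rank_regression(tab)
  expect_named(fit$models, c("standard", "noisy", "probabilistic_ending",
                             "noisy_probabilistic_ending"))
  all_co <- suppressWarnings(tidy(fit))   # sigma = 0: perfect-fit warning
  all_gl <- suppressWarnings(glance(fit))
  for (type in names(fit$models)) {
    co <- all_co[all_co$tournament_type == type, ]
    # clipping never bites at these defaults, so recovery is exact
    for (feat in names(spec$betas)) {
      if (feat %in% co$term) {
        expect_equal(co$estimate[co$term == feat], unname(spec$betas[feat]),
                     tolerance = 1e-8,
                     label = paste(type, feat))
      }
    }
    expect_equal(co$estimate[co$term == "(Intercept)"], spec$intercept,
                 tolerance = 1e-8)
    # planted features absent from the design leave no signal behind:
    # the fit explains the response completely
    expect_gte(all_gl$r.squared[all_gl$tournament_type == type], 1 - 1e-10)
  }
})

test_that("regression residuals are orthogonal to the design", {
  tab <- generate_feature_table(synthetic_spec(n_tournaments = 20,
                                               seed = 4))
  fit <- fit_rank_regression(tab)
  for (m in fit$models) {
    X <- stats::model.matrix(m)
    expect_lt(max(abs(crossprod(X, stats::residuals(m)))), 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  tab <- generate_feature_table(synthetic_spec(n_tournaments = 10,
                                               types = "standard",
                                               seed = 5))
  tab$C_min_over_C_r <- 2 * tab$SSE  # duplicate information
  expect_error(
    fit_rank_regression(tab, feature_lists = list(
      standard = c("SSE", "C_min_over_C_r"))),
    "collinear.*C_min_over_C_r")
})

test_that("too few rows for the design is an informative error", {
  tab <- generate_feature_table(synthetic_spec(
    n_tournaments = 1, types = "standard", n_strategies = c(3, 3),
    seed = 6))
  expect_error(fit_rank_regression(tab), "not enough complete rows")
})

test_that("planted coefficients fall inside their 95% CI at the nominal rate", {
  spec_betas <- c(CD_to_C = 0.15, SSE = 0.12, CC_to_C = -0.12)
  hits <- matrix(NA, 100, length(spec_betas),
                 dimnames = list(NULL, names(spec_betas)))
  for (s in 1:100) {
    tab <- generate_feature_table(synthetic_spec(
      n_tournaments = 30, types = "standard", betas = spec_betas,
      sigma = 0.05, seed = 7000 + s))
    fit <- fit_rank_regression(tab, feature_lists = list(
      standard = names(spec_betas)))
    co <- tidy(fit)
    for (feat in names(spec_betas)) {
      row <- co[co$term == feat, ]
      lo <- row$estimate - qt(0.975, glance(fit)$df.residual) * row$std.error
      hi <- row$estimate + qt(0.975, glance(fit)$df.residual) * row$std.error
      hits[s, feat] <- lo <= spec_betas[feat] && spec_betas[feat] <= hi
    }
  }
  expect_true(all(colMeans(hits) >= 0.93))
})

test_that("winner profiles describe only the rank-0 rows", {
  tab <- generate_feature_table(synthetic_spec(n_tournaments = 15,
                                               seed = 8))
  prof <- winner_profiles(tab)
  # one winner per tournament block of each type
  n_blocks <- nrow(dplyr::distinct(tab, .data$tournament_type, .data$trial))
  expect_equal(nrow(dplyr::filter(prof$winners, .data$feature == "SSE")),
               n_blocks)
  expect_true(all(prof$summary$n <= 15))

  flat <- tab
  flat$C_r_over_C_mean[flat$rank == 0] <- 1
  pf <- winner_profiles(flat)
  med <- pf$summary[pf$summary$feature == "C_r_over_C_mean", ]
  expect_true(all(med$median == 1))

  defectors <- tab
  defectors$C_r[defectors$rank == 0] <- 0
  pd <- winner_profiles(defectors)
  cr <- pd$summary[pd$summary$feature == "C_r", ]
  expect_true(all(cr$max == 0))
})

test_that("campaign output flows through the whole analysis layer", {
  camp <- run_campaign(3, seed = 71)
  cors <- correlate_features(camp$features)
  expect_true(all(abs(cors$estimate) <= 1 + 1e-12))
  prof <- winner_profiles(camp$features)
  sse <- prof$summary[prof$summary$feature == "SSE", ]
  expect_true(all(sse$min >= 0))
  expect_equal(sort(unique(prof$winners$tournament_type)),
               sort(unique(camp$features$tournament_type)))
})
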