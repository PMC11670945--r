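test_that("the three-strategy worked example scores and ranks correctly", {
  s <- run_tournament(c("Cooperator", "Defector", "Tit For Tat"),
                      n = 10, k = 1, seed = 1)
  expect_equal(s$name, c("Defector", "Tit For Tat", "Cooperator"))
  expect_equal(s$median_score, c(3.2, 1.95, 1.5))
  expect_equal(s$rank, c(0L, 1L, 2L))
  # Defector beats both opponents on match totals
  expect_equal(s$wins[s$name == "Defector"], 2)
  expect_equal(s$wins[s$name == "Cooperator"], 0)
})

test_that("an all-cooperator population is fully cooperative", {
  s <- run_tournament(rep("Cooperator", 3), n = 12, k = 2, seed = 4)
  expect_equal(s$median_score, rep(3, 3))
  expect_equal(s$cooperation_rating, rep(1, 3))
  expect_equal(s$CC_rate, rep(1, 3))
  expect_equal(s$CC_to_C, rep(1, 3))
  expect_true(all(is.na(s$CD_to_C)))
  expect_true(all(is.na(s$DD_to_C)))
  # ties resolved by name order, still a permutation
  expect_equal(sort(s$rank), 0:2)
  expect_equal(s$name[s$rank == 0L], "Cooperator")
})

test_that("tournaments are deterministic and k-invariant without noise", {
  players <- c("Tit For Tat", "Grudger", "Alternator", "Defector")
  a <- run_tournament(players, n = 20, k = 1, seed = 9)
  b <- run_tournament(players, n = 20, k = 1, seed = 9)
  expect_identical(a, b)
  # deterministic strategies: every repetition replays the same matches
  c3 <- run_tournament(players, n = 20, k = 3, seed = 9)
  expect_equal(c3$median_score, a$median_score)
  expect_equal(c3$rank, a$rank)
  expect_equal(c3$wins, a$wins)
})

test_that("ranks are a permutation of 0..N-1 on random tournaments", {
  set.seed(31)
  pool <- ipd_catalog()$name
  for (i in 1:5) {
    N <- sample(3:6, 1)
    s <- run_tournament(sample(pool, N), p_e = 0.2, p_n = 0.05, k = 2,
                        seed = i)
    expect_setequal(s$rank, 0:(N - 1))
    expect_equal(s$rank, sort(s$rank))  # rows ordered by rank
    rates <- s[, c("CC_rate", "CD_rate", "DC_rate", "DD_rate")]
    expect_equal(rowSums(rates), rep(1, N), tolerance = 1e-12)
    cond <- unlist(s[, c("CC_to_C", "CD_to_C", "DC_to_C", "DD_to_C")])
    expect_true(all(is.na(cond) | (cond >= 0 & cond <= 1)))
  }
})

test_that("behavior summary matches the hand-traced TFT vs Defector match", {
  m <- play_match("Tit For Tat", "Defector", match_config(n = 5))
  b <- summarize_behavior(m)
  tft <- b[b$name == "Tit For Tat", ]
  expect_equal(tft$CD_rate, 0.2)
  expect_equal(tft$DD_rate, 0.8)
  expect_equal(tft$CD_to_C, 0)
  expect_equal(tft$DD_to_C, 0)
  expect_true(is.na(tft$CC_to_C))
  expect_equal(tft$initial_C, 1)
  expect_equal(b$wins[b$name == "Defector"], 1)
  expect_equal(b$wins[b$name == "Tit For Tat"], 0)
})

test_that("state rates mirror between the two players of a match", {
  m <- play_match("Gradual", "Alternator", match_config(n = 31, seed = 2))
  b <- summarize_behavior(m)
  g <- b[b$name == "Gradual", ]
  a <- b[b$name == "Alternator", ]
  expect_equal(g$CD_rate, a$DC_rate)
  expect_equal(g$DC_rate, a$CD_rate)
  expect_equal(g$CC_rate, a$CC_rate)
  expect_equal(g$DD_rate, a$DD_rate)
})

test_that("score ranks order descending with deterministic tie-breaks", {
  expect_equal(score_ranks(c(3.2, 1.95, 1.5)), c(0L, 1L, 2L))
  expect_equal(score_ranks(c(1.0, 2.0)), c(1L, 0L))
  expect_equal(score_ranks(c(2, 2, 2), c("b", "a", "c")), c(1L, 0L, 2L))
})

test_that("self-pairs never affect scoring or ranking", {
  players <- c("Grudger", "Alternator", "Win-Stay Lose-Shift")
  with_self <- run_tournament(players, n = 15, k = 1, seed = 6,
                              self_play = TRUE)
  without <- run_tournament(players, n = 15, k = 1, seed = 6,
                            self_play = FALSE)
  expect_equal(with_self$median_score, without$median_score)
  expect_equal(with_self$rank, without$rank)
  expect_equal(with_self$wins, without$wins)
  # but self-matches do enter the pooled behavior statistics
  expect_false(isTRUE(all.equal(with_self$CC_rate, without$CC_rate)))
})

test_that("ranking can switch to the mean over repetitions", {
  players <- c("Random", "Tit For Tat", "Defector")
  med <- run_tournament(players, n = 10, k = 5, seed = 13)
  avg <- run_tournament(players, n = 10, k = 5, seed = 13,
                        rank_by = "mean")
  expect_setequal(avg$rank, 0:2)
  expect_equal(sort(avg$name), sort(med$name))
})

test_that("degenerate tournaments are rejected", {
  expect_error(run_tournament("Cooperator", n = 5), "at least 2")
  expect_error(run_tournament(c("Cooperator", "Defector"), n = 5, k = 0),
               "`k`")
  expect_error(run_tournament(c("Cooperator", "Defector")),
               "one of `n` and `p_e`")
})
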