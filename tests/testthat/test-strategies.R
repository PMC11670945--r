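test_that("deterministic catalog strategies reproduce their golden traces", {
  traces <- golden_traces()
  for (i in seq_len(nrow(traces))) {
    row <- traces[i, ]
    expect_equal(trace_actions(row$strategy, "Cooperator"),
                 row$vs_cooperator,
                 label = paste(row$strategy, "vs Cooperator"))
    expect_equal(trace_actions(row$strategy, "Defector"),
                 row$vs_defector,
                 label = paste(row$strategy, "vs Defector"))
    expect_equal(trace_actions(row$strategy, "Alternator"),
                 row$vs_alternator,
                 label = paste(row$strategy, "vs Alternator"))
  }
})

test_that("classifier metadata matches the strategy definitions", {
  cat <- ipd_catalog()
  expect_false(anyDuplicated(cat$name) > 0)
  expect_equal(classify("Tit For Tat")$memory_size, 1)
  expect_false(classify("Tit For Tat")$makes_use_of_game)
  expect_false(classify("Tit For Tat")$makes_use_of_length)
  expect_equal(classify("Grudger")$memory_size, Inf)
  expect_true(classify("Random")$stochastic)
  expect_true(classify("ZD-Extort-2")$stochastic)
  expect_equal(classify("ZD-Extort-2")$memory_size, 1)
  expect_true(classify("BackStabber")$makes_use_of_length)
  expect_true(classify("Generous Tit For Tat")$makes_use_of_game)
  expect_error(make_strategy("No Such Strategy"), "unknown strategy")
})

test_that("generous TFT forgives at the standard generosity", {
  expect_equal(gtft_generosity(), 1 / 3)
  m <- play_match("Generous Tit For Tat", "Defector",
                  match_config(n = 10000L, seed = 5))
  forgave <- mean(m$actions_a[-1] == "C")
  expect_lt(abs(forgave - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 9999))
  # ... and never defects first against a cooperator
  expect_equal(trace_actions("Generous Tit For Tat", "Cooperator"),
               "CCCCCCCCCC")
})

test_that("a (1,0,1,0) memory-one vector is behaviorally TFT", {
  m1 <- memory_one_strategy("M1", c(1, 0, 1, 0))
  for (opp in c("Alternator", "Defector", "Gradual", "Random")) {
    a <- play_match(m1, opp, match_config(n = 30, seed = 42))
    b <- play_match("Tit For Tat", opp, match_config(n = 30, seed = 42))
    expect_identical(a$actions_a, b$actions_a, label = paste("vs", opp))
    expect_identical(a$actions_b, b$actions_b, label = paste("vs", opp))
  }
})

test_that("zero-determinant catalog vectors are exactly extortionate", {
  fit <- sse_to_zd(c(8 / 9, 1 / 2, 1 / 3, 0))
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  expect_equal(fit$phi, 1 / 18, tolerance = 1e-9)
  expect_equal(fit$chi, 2, tolerance = 1e-9)
})

test_that("strategy objects are reusable: same seed, same match", {
  s <- make_strategy("Gradual")
  cfg <- match_config(n = 40, p_n = 0.2, seed = 17)
  first <- play_match(s, "Random", cfg)
  second <- play_match(s, "Random", cfg)
  expect_identical(first, second)
})

test_that("a majority ensemble of identical members equals the member", {
  trio <- meta_majority(team = list("Tit For Tat", "Tit For Tat",
                                    "Tit For Tat"), name = "Three TFT")
  for (opp in c("Alternator", "Defector", "Cooperator")) {
    expect_equal(trace_actions(trio, opp), trace_actions("Tit For Tat", opp),
                 label = paste("vs", opp))
  }
})

test_that("generic FSM and lookup strategies replay catalog rules", {
  fsm_grudger <- fsm_strategy("FSM Grudger",
    transitions = data.frame(
      state = c(1, 1, 2, 2), input = c("C", "D", "C", "D"),
      next_state = c(1, 2, 2, 2), action = c("C", "D", "D", "D")),
    initial_state = 1, initial_action = "C")
  lu_tft <- lookup_strategy("LU TFT",
    table = c("C|C" = "C", "C|D" = "D", "D|C" = "C", "D|D" = "D"),
    depth = 1, opening = "C")
  for (opp in c("Cooperator", "Defector", "Alternator")) {
    expect_equal(trace_actions(fsm_grudger, opp),
                 trace_actions("Grudger", opp))
    expect_equal(trace_actions(lu_tft, opp),
                 trace_actions("Tit For Tat", opp))
  }
})

test_that("generic constructors validate their rule tables", {
  expect_error(memory_one_strategy("bad", c(1, 0, 2, 0)),
               "four probabilities")
  expect_error(
    fsm_strategy("bad", data.frame(state = 1, input = "C",
                                   next_state = 1, action = "C"),
                 initial_state = 1, initial_action = "C"),
    "incomplete transition table")
  expect_error(
    fsm_strategy("bad", data.frame(state = c(1, 1, 1), input = c("C", "D", "C"),
                                   next_state = 1, action = "C"),
                 initial_state = 1, initial_action = "C"),
    "duplicate \\(state, input\\)")
  expect_error(
    lookup_strategy("bad", c("C|C" = "C"), depth = 1, opening = "C"),
    "missing keys")
  expect_error(
    lookup_strategy("bad", c("C|C" = "C"), depth = 2, opening = "C"),
    "at least `depth`")
})

test_that("strategies load from a config file and behave as specified", {
  path <- system.file("extdata", "example-strategies.yaml",
                      package = "ipdsim")
  loaded <- read_strategy_config(path)
  expect_named(loaded, c("Example Memory One", "Example FSM Grudge",
                         "Example Lookup TFT"))
  for (opp in c("Defector", "Alternator")) {
    expect_equal(trace_actions(loaded[["Example Lookup TFT"]], opp),
                 trace_actions("Tit For Tat", opp))
    expect_equal(trace_actions(loaded[["Example FSM Grudge"]], opp),
                 trace_actions("Grudger", opp))
  }
  expect_true(classify(loaded[["Example Memory One"]])$stochastic)
})

test_that("malformed strategy configs are rejected with context", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("strategies:",
               "  - name: Broken",
               "    type: memory_one",
               "    vector: [1, 0, 1]"), bad)
  expect_error(read_strategy_config(bad), "Broken")
  writeLines(c("strategies:",
               "  - name: Dup", "    type: memory_one",
               "    vector: [1, 0, 1, 0]",
               "  - name: Dup", "    type: memory_one",
               "    vector: [1, 1, 1, 0]"), bad)
  expect_error(read_strategy_config(bad), "duplicate")
  writeLines("foo: 1", bad)
  expect_error(read_strategy_config(bad), "strategies")
})
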