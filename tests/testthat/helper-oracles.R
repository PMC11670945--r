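# Independent oracles used across the suite. These deliberately avoid the
# package's analytic code paths.

# Focal action trace of a noise-free match, as a compact string.
trace_actions <- function(strategy, opponent, n = 10, seed = 1) {
  m <- play_match(strategy, opponent, match_config(n = n, seed = seed))
  paste(m$actions_a, collapse = "")
}

# Spearman by definition: average-rank transform, then Pearson computed
# from sums (no call to cor()).
brute_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exhaustive grid search for the SSE-to-ZD projection over
# (a, b) in [0, a_max] x [0, b_max]: coarse pass, then a fine local
# refinement around the coarse minimum. The objective is evaluated from
# its quadratic expansion, vectorized over the grid.
grid_sse <- function(p, payoffs = payoff_matrix(), a_max = 5, b_max = 5,
                     coarse = 0.02, fine = 2e-4) {
  p_tilde <- p + c(-1, -1, 0, 0)
  u <- c(payoffs$R, payoffs$S, payoffs$T, payoffs$P) - payoffs$P
  v <- c(payoffs$R, payoffs$T, payoffs$S, payoffs$P) - payoffs$P
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  up <- sum(u * p_tilde); vp <- sum(v * p_tilde); pp <- sum(p_tilde^2)
  eval_grid <- function(as, bs) {
    m <- outer(as^2 * uu - 2 * as * up, rep(1, length(bs))) +
      outer(rep(1, length(as)), bs^2 * vv + 2 * bs * vp) -
      2 * uv * outer(as, bs) + pp
    idx <- which(m == min(m), arr.ind = TRUE)[1, ]
    list(a = as[idx[1]], b = bs[idx[2]], sse = min(m))
  }
  g <- eval_grid(seq(0, a_max, by = coarse), seq(0, b_max, by = coarse))
  g <- eval_grid(seq(max(0, g$a - 2 * coarse), g$a + 2 * coarse, by = fine),
                 seq(max(0, g$b - 2 * coarse), g$b + 2 * coarse, by = fine))
  g
}

# Hand-written 10-round action traces for every deterministic catalog
# strategy against the three reference opponents (noise-free, n = 10, so
# length-aware strategies see n = 10). Derived move by move from the
# rule statements, independently of the engine.
golden_traces <- function() {
  tibble::tribble(
    ~strategy,                ~vs_cooperator, ~vs_defector,  ~vs_alternator,
    "Cooperator",             "CCCCCCCCCC",   "CCCCCCCCCC",  "CCCCCCCCCC",
    "Defector",               "DDDDDDDDDD",   "DDDDDDDDDD",  "DDDDDDDDDD",
    "Alternator",             "CDCDCDCDCD",   "CDCDCDCDCD",  "CDCDCDCDCD",
    "Tit For Tat",            "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDCDCDCDC",
    "Suspicious Tit For Tat", "DCCCCCCCCC",   "DDDDDDDDDD",  "DCDCDCDCDC",
    "Tit For 2 Tats",         "CCCCCCCCCC",   "CCDDDDDDDD",  "CCCCCCCCCC",
    "Two Tits For Tat",       "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDDDDDDDD",
    "Grudger",                "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDDDDDDDD",
    "Spiteful Tit For Tat",   "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDCDCDCDC",
    "Fool Me Once",           "CCCCCCCCCC",   "CCDDDDDDDD",  "CCCCDDDDDD",
    "Win-Stay Lose-Shift",    "CCCCCCCCCC",   "CDCDCDCDCD",  "CCDDCCDDCC",
    "Gradual",                "CCCCCCCCCC",   "CDCCDDDDCC",  "CCDCCCDDDC",
    "Adaptive Tit For Tat",   "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDCDCDCDC",
    "Omega TFT",              "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDCDCDDDD",
    "Prober",                 "DCCDDDDDDD",   "DCCDDDDDDD",  "DCCCDCDCDC",
    "BackStabber",            "CCCCCCCCDD",   "CCCCDDDDDD",  "CCCCCCCCDD",
    "Meta Majority",          "CCCCCCCCCC",   "CDDDDDDDDD",  "CCDDDDDDDD",
    "Meta Winner",            "CDDDDDDDDD",   "CDDDDDDDDD",  "CDDDDDDDDD"
  )
}
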