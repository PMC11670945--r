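#' Sampling ranges for randomized tournament trials
#'
#' A trial draws a tournament size `N`, a repetition count `k`, a number
#' of turns `n`, a noise probability `p_n`, and an ending probability
#' `p_e`, each uniformly from its range. `trial_ranges()` defaults to the
#' full study ranges (`N` in `[3, 195]` — clipped to the catalog size at
#' sampling time — `k` in `[10, 100]`, `n` in `[1, 200]`, `p_n` in
#' `[0, 1]`, `p_e` in `(0, 1]`); `desk_ranges()` is a small profile for
#' interactive work and smoke runs that completes in seconds.
#'
#' @param n_strategies,k,n Integer ranges, `c(lo, hi)`.
#' @param p_n,p_e Probability ranges, `c(lo, hi)`; `p_e` draws exclude an
#'   exact 0 (a match that never ends).
#' @return A list of class `ipd_trial_ranges`.
#' @examples
#' trial_ranges()
#' desk_ranges()
#' @export
trial_ranges <- function(n_strategies = c(3L, 195L), k = c(10L, 100L),
                         n = c(1L, 200L), p_n = c(0, 1), p_e = c(0, 1)) {
  check_range <- function(x, arg, lo_min = 1) {
    if (length(x) != 2 || any(is.na(x)) || x[1] > x[2] || x[1] < lo_min) {
      stop("`", arg, "` must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
    x
  }
  structure(
    list(n_strategies = as.integer(check_range(n_strategies, "n_strategies", 2)),
         k = as.integer(check_range(k, "k")),
         n = as.integer(check_range(n, "n")),
         p_n = check_range(p_n, "p_n", 0),
         p_e = check_range(p_e, "p_e", 0)),
    class = "ipd_trial_ranges"
  )
}

#' @rdname trial_ranges
#' @export
desk_ranges <- function() {
  trial_ranges(n_strategies = c(3L, 8L), k = c(2L, 4L), n = c(5L, 40L),
               p_n = c(0, 0.2), p_e = c(0.1, 1))
}

#' @export
print.ipd_trial_ranges <- function(x, ...) {
  cat("<ipd_trial_ranges>\n")
  cat("  N in [", x$n_strategies[1], ", ", x$n_strategies[2],
      "], k in [", x$k[1], ", ", x$k[2],
      "], n in [", x$n[1], ", ", x$n[2], "]\n", sep = "")
  cat("  p_n in [", x$p_n[1], ", ", x$p_n[2],
      "], p_e in (", x$p_e[1], ", ", x$p_e[2], "]\n", sep = "")
  invisible(x)
}

#' Sample one randomized trial configuration
#'
#' Draws, in order: the tournament size `N` (uniform integer), `N`
#' distinct strategies without replacement from the catalog, then `k`,
#' `n`, `p_n`, and `p_e` from their ranges. The draw is fully determined
#' by `seed`.
#'
#' @param seed Integer seed for the trial.
#' @param ranges An [trial_ranges()] object.
#' @param catalog A catalog tibble as returned by [ipd_catalog()] (or any
#'   tibble with a `name` column of registered strategy names).
#' @return A list of class `ipd_trial_config` with fields `seed`,
#'   `players`, `N`, `k`, `n`, `p_n`, `p_e`.
#' @examples
#' sample_trial(1, desk_ranges())
#' @export
sample_trial <- function(seed, ranges = trial_ranges(),
                         catalog = ipd_catalog()) {
  stopifnot(inherits(ranges, "ipd_trial_ranges"))
  pool <- catalog$name
  if (length(pool) < 2) stop("catalog must contain at least 2 strategies",
                             call. = FALSE)
  set.seed(as.integer(seed))
  n_max <- min(ranges$n_strategies[2], length(pool))
  n_min <- min(ranges$n_strategies[1], n_max)
  N <- sample(n_min:n_max, 1L)
  players <- sample(pool, N)
  k <- sample(ranges$k[1]:ranges$k[2], 1L)
  n <- sample(ranges$n[1]:ranges$n[2], 1L)
  p_n <- runif(1, ranges$p_n[1], ranges$p_n[2])
  # p_e = hi - u * (hi - lo) lies in (lo, hi]: excludes a never-ending match.
  p_e <- ranges$p_e[2] - runif(1) * (ranges$p_e[2] - ranges$p_e[1])
  structure(
    list(seed = as.integer(seed), players = players, N = N, k = k, n = n,
         p_n = p_n, p_e = p_e),
    class = "ipd_trial_config"
  )
}

#' @export
print.ipd_trial_config <- function(x, ...) {
  cat("<ipd_trial_config> seed ", x$seed, ": N = ", x$N, ", k = ", x$k,
      ", n = ", x$n, ", p_n = ", round(x$p_n, 4),
      ", p_e = ", round(x$p_e, 4), "\n", sep = "")
  cat("  players: ", paste(x$players, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the four tournaments of one trial
#'
#' Executes, on the same players with the same `k`: a standard
#' tournament (`n` turns, no noise), a noisy tournament (`n` turns,
#' noise `p_n`), a probabilistic-ending tournament (`p_e`, no noise),
#' and a noisy probabilistic-ending tournament (`p_n` and `p_e`). Each
#' tournament receives a child seed derived from the trial seed, so the
#' whole trial is reproducible.
#'
#' @param config An [sample_trial()] result (or a compatible list).
#' @param payoffs An [payoff_matrix()] object.
#' @param self_play Passed to [run_tournament()].
#' @param length_cap Passed to [run_tournament()].
#' @return A list of class `ipd_trial`: `config` plus `summaries`, a
#'   named list of four `ipd_result_summary` tibbles.
#' @examples
#' tr <- run_trial(sample_trial(1, desk_ranges()))
#' names(tr$summaries)
#' @export
run_trial <- function(config, payoffs = payoff_matrix(), self_play = TRUE,
                      length_cap = 10000L) {
  stopifnot(is.list(config),
            all(c("seed", "players", "k", "n", "p_n", "p_e") %in%
                  names(config)))
  s <- config$seed
  common <- list(players = config$players, k = config$k, payoffs = payoffs,
                 self_play = self_play, length_cap = length_cap)
  summaries <- list(
    standard = do.call(run_tournament, c(common, list(
      n = config$n, p_n = 0, seed = derive_seed(s, 101L)))),
    noisy = do.call(run_tournament, c(common, list(
      n = config$n, p_n = config$p_n, seed = derive_seed(s, 102L)))),
    probabilistic_ending = do.call(run_tournament, c(common, list(
      p_e = config$p_e, p_n = 0, seed = derive_seed(s, 103L)))),
    noisy_probabilistic_ending = do.call(run_tournament, c(common, list(
      p_e = config$p_e, p_n = config$p_n, seed = derive_seed(s, 104L))))
  )
  structure(list(config = config, summaries = summaries),
            class = "ipd_trial")
}

#' @export
print.ipd_trial <- function(x, ...) {
  print(x$config)
  for (type in names(x$summaries)) {
    winner <- x$summaries[[type]]$name[1L]
    cat("  ", format(gsub("_", " ", type), width = 28), " winner: ",
        winner, "\n", sep = "")
  }
  invisible(x)
}

#' Feature table of one trial
#'
#' Binds the [summary_features()] of the trial's four tournaments.
#'
#' @param trial An [run_trial()] result.
#' @param trial_id Integer identifier written to the `trial` column
#'   (defaults to the trial seed).
#' @return A tibble with one row per (tournament type, strategy).
#' @export
trial_features <- function(trial, trial_id = NULL) {
  stopifnot(inherits(trial, "ipd_trial"))
  trial_id <- trial_id %||% trial$config$seed
  purrr::list_rbind(purrr::map(
    unname(trial$summaries), summary_features, trial_id = trial_id))
}

trial_config_row <- function(config, trial_id) {
  tibble::tibble(
    trial = as.integer(trial_id),
    seed = as.integer(config$seed),
    N = as.integer(config$N),
    k = as.integer(config$k),
    n = as.integer(config$n),
    p_n = config$p_n,
    p_e = config$p_e,
    players = paste(config$players, collapse = "; ")
  )
}

empty_trial_table <- function() {
  tibble::tibble(trial = integer(), seed = integer(), N = integer(),
                 k = integer(), n = integer(), p_n = double(),
                 p_e = double(), players = character())
}

#' Run a campaign of randomized trials
#'
#' Samples and runs `n_trials` independent trials (four tournaments
#' each), collecting one trial table and one feature table. Trials
#' derive their seeds from `seed`, so a campaign is reproducible and —
#' with `out_dir` — resumable: completed trial indices are recorded in a
#' manifest, and a resumed campaign skips them and appends only the
#' missing ones; the returned tables equal those of an uninterrupted
#' run.
#'
#' @param n_trials Number of trials (0 is allowed and yields empty
#'   tables with valid headers).
#' @param seed Master seed for the campaign.
#' @param ranges An [trial_ranges()] object; the default [desk_ranges()]
#'   keeps a smoke run in the seconds range.
#' @param catalog Strategy catalog tibble, see [ipd_catalog()].
#' @param out_dir Optional output directory; when given, `trials.csv`,
#'   `features.csv`, and `manifest.yaml` are written/appended there.
#' @param resume Continue a previously interrupted campaign in
#'   `out_dir`?
#' @param payoffs,self_play,length_cap Passed to [run_trial()].
#' @return Invisibly, `list(trials = , features = )` of tibbles.
#' @examples
#' \donttest{
#' camp <- run_campaign(2, seed = 1)
#' camp$trials
#' }
#' @export
run_campaign <- function(n_trials, seed, ranges = desk_ranges(),
                         catalog = ipd_catalog(), out_dir = NULL,
                         resume = FALSE, payoffs = payoff_matrix(),
                         self_play = TRUE, length_cap = 10000L) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 0)
  done <- integer(0)
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(out_dir, "manifest.yaml")
    if (resume && file.exists(manifest_path)) {
      manifest <- yaml::read_yaml(manifest_path)
      if (!identical(as.integer(manifest$seed), as.integer(seed))) {
        stop("manifest seed does not match `seed`; refusing to resume",
             call. = FALSE)
      }
      done <- as.integer(manifest$completed)
    }
  }
  trials <- list()
  features <- list()
  for (t in seq_len(n_trials)) {
    if (t %in% done) next
    cfg <- sample_trial(derive_seed(seed, 5000L, t), ranges, catalog)
    tr <- run_trial(cfg, payoffs = payoffs, self_play = self_play,
                    length_cap = length_cap)
    trow <- trial_config_row(cfg, t)
    frows <- trial_features(tr, trial_id = t)
    trials[[length(trials) + 1L]] <- trow
    features[[length(features) + 1L]] <- frows
    if (!is.null(out_dir)) {
      tpath <- file.path(out_dir, "trials.csv")
      fpath <- file.path(out_dir, "features.csv")
      readr::write_csv(trow, tpath, append = file.exists(tpath), na = "")
      readr::write_csv(frows, fpath, append = file.exists(fpath), na = "")
      done <- sort(c(done, t))
      yaml::write_yaml(
        list(seed = as.integer(seed), n_trials = n_trials,
             ranges = unclass(ranges), completed = done),
        manifest_path)
    }
  }
  trials <- if (length(trials)) purrr::list_rbind(trials) else empty_trial_table()
  features <- if (length(features)) purrr::list_rbind(features) else empty_feature_table()
  if (!is.null(out_dir)) {
    if (n_trials == 0) {
      readr::write_csv(trials, file.path(out_dir, "trials.csv"), na = "")
      readr::write_csv(features, file.path(out_dir, "features.csv"), na = "")
    } else if (resume) {
      # Return the complete tables, including trials finished earlier.
      trials <- read_trial_table(file.path(out_dir, "trials.csv"))
      features <- read_feature_table(file.path(out_dir, "features.csv"))
      trials <- trials[order(trials$trial), ]
      features <- features[order(features$trial), ]
    }
  }
  invisible(list(trials = trials, features = features))
}
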