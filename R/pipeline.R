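#' Run the aggregate trend analysis for one emotion
#'
#' Chains the full single-trend pipeline: inclusion filter (at least one
#' message; loneliness additionally requires a struggle score > 5), raw to
#' reporting scale conversion, gridding onto the minute grid, aggregation
#' across users, onset detection, and the percent-change summary. The
#' filter funnel (total sessions, sessions with messages, sessions included
#' for the emotion) is always returned and logged via `message()` unless
#' `quiet = TRUE`.
#'
#' @param corpus A [chat_corpus()] or path to a JSONL transcript file.
#' @param scores Score replay table (tibble) or path to a score CSV.
#' @param emotion An [emotion_spec()] or emotion name.
#' @param reference_minute Reference grid minute (default 5).
#' @param alpha Significance level (default 0.05).
#' @param grid_max Last grid minute (default 68).
#' @param summary_at Intermediate time for the second percent change.
#' @param out_dir If non-`NULL`, write `<emotion>_trend.csv` and
#'   `<emotion>_summary.json` there.
#' @param quiet Suppress funnel logging.
#' @return List with `trend` (an [aggregate_trend()]), `summary`
#'   (see [trend_summary()]), and `funnel` (named counts: `total`,
#'   `with_messages`, `included`).
#' @export
run_trend <- function(corpus, scores, emotion, reference_minute = 5,
                      alpha = 0.05, grid_max = 68, summary_at = 19.4,
                      out_dir = NULL, quiet = TRUE) {
  if (is.character(corpus)) corpus <- read_sessions(corpus)
  if (is.character(scores)) scores <- read_score_table(scores)
  if (is.character(emotion)) emotion <- emotion_spec(emotion)

  sess <- corpus$sessions
  s0 <- struggle_scores(scores, emotion$name)
  key <- paste(sess$session_key, sess$user_id, sep = "\r")
  raw0 <- s0$value[match(key, paste(s0$session_key, s0$user_id, sep = "\r"))]
  inc <- include_session(emotion, raw0, sess$message_count)
  funnel <- c(total = nrow(sess),
              with_messages = sum(sess$message_count >= 1L),
              included = sum(inc))
  if (!quiet) {
    message(sprintf(
      "[%s] funnel: %d sessions -> %d with messages -> %d included",
      emotion$name, funnel[["total"]], funnel[["with_messages"]],
      funnel[["included"]]))
  }
  if (funnel[["included"]] < 2L) {
    ptr_error(sprintf(
      "no analyzable %s sessions: %d of %d passed the inclusion filter",
      emotion$name, funnel[["included"]], funnel[["total"]]),
      "ptr_empty_filter_error")
  }
  traj <- trajectory_matrix(scores, sess$session_key[inc],
                            sess$user_id[inc], emotion,
                            grid_max = grid_max)
  trend <- aggregate_trend(traj, emotion,
                           reference_minute = reference_minute)
  summ <- trend_summary(trend, at = summary_at, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trend(trend, file.path(out_dir,
                                 paste0(emotion$name, "_trend.csv")))
    jsonlite::write_json(
      c(summ, list(funnel = as.list(funnel))),
      file.path(out_dir, paste0(emotion$name, "_summary.json")),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  list(trend = trend, summary = summ, funnel = funnel)
}

#' Run the matched-cohort comparison for one emotion
#'
#' Chains cohort split, propensity fit, caliper matching, the per-emotion
#' inclusion filter inside each matched cohort, both cohort trends, and the
#' minute-by-minute between-cohort test.
#'
#' @inheritParams run_trend
#' @param caliper_fraction Fraction of pooled propensity SD (default 0.25).
#' @param group_min_users See [split_cohorts()].
#' @param seed Tie-break seed for the matcher.
#' @return List with `match` (a `match_result`), `comparison` (see
#'   [compare_cohorts()]), and `funnel` (named counts: `single`, `group`,
#'   `pairs`, `single_included`, `group_included`).
#' @export
run_compare <- function(corpus, scores, emotion, caliper_fraction = 0.25,
                        group_min_users = 2L, seed = 1L,
                        reference_minute = 5, alpha = 0.05, grid_max = 68,
                        out_dir = NULL, quiet = TRUE) {
  if (is.character(corpus)) corpus <- read_sessions(corpus)
  if (is.character(scores)) scores <- read_score_table(scores)
  if (is.character(emotion)) emotion <- emotion_spec(emotion)

  match_res <- propensity_match(corpus, scores, emotion,
                                caliper_fraction = caliper_fraction,
                                group_min_users = group_min_users,
                                seed = seed)
  if (nrow(match_res$pairs) == 0L) {
    ptr_error("no matched pairs within the caliper", "ptr_empty_filter_error")
  }
  cmp <- compare_cohorts(match_res, scores, emotion,
                         reference_minute = reference_minute,
                         alpha = alpha, grid_max = grid_max)
  funnel <- c(
    single = sum(match_res$sessions$cohort == "single"),
    group = sum(match_res$sessions$cohort == "group"),
    pairs = nrow(match_res$pairs),
    single_included = cmp$n_single,
    group_included = cmp$n_group
  )
  if (!quiet) {
    message(sprintf(
      "[%s] cohorts: %d single / %d group -> %d pairs -> %d / %d after filter",
      emotion$name, funnel[["single"]], funnel[["group"]],
      funnel[["pairs"]], funnel[["single_included"]],
      funnel[["group_included"]]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trend(cmp$trend_single,
                file.path(out_dir, paste0(emotion$name, "_single_trend.csv")))
    write_trend(cmp$trend_group,
                file.path(out_dir, paste0(emotion$name, "_group_trend.csv")))
    report <- list(
      emotion = emotion$name,
      caliper = match_res$caliper,
      seed = match_res$seed,
      n_pairs = nrow(match_res$pairs),
      divergence_minute = cmp$divergence_minute,
      funnel = as.list(funnel),
      balance = match_res$balance,
      pairs = match_res$pairs
    )
    jsonlite::write_json(report,
                         file.path(out_dir,
                                   paste0(emotion$name, "_match.json")),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  list(match = match_res, comparison = cmp, funnel = funnel)
}

#' Simulate a corpus and write its artifacts
#'
#' Wraps [generate_corpus()]: writes `corpus.jsonl`, `scores.csv`,
#' `scores_noisefree.csv`, `truth.json` (latent parameters and grids), and
#' a `manifest.json` carrying the resolved configuration, seed, package
#' version and output digests. Identical config and seed give identical
#' outputs.
#'
#' @param config A [generator_config()] (or a list of config overrides).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return The [generate_corpus()] result, invisibly.
#' @export
run_simulate <- function(config = generator_config(), seed = 1L, out_dir) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  sim <- generate_corpus(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sessions(sim$corpus, file.path(out_dir, "corpus.jsonl"))
  write_score_table(sim$scores, file.path(out_dir, "scores.csv"))
  write_score_table(sim$truth$scores_noisefree,
                    file.path(out_dir, "scores_noisefree.csv"))
  jsonlite::write_json(
    list(params = sim$truth$params,
         latent_loneliness = unname(split(sim$truth$latent_loneliness,
                                          row(sim$truth$latent_loneliness))),
         latent_optimism = unname(split(sim$truth$latent_optimism,
                                        row(sim$truth$latent_optimism))),
         seed = seed),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  write_manifest(out_dir, config, seed,
                 c("corpus.jsonl", "scores.csv", "scores_noisefree.csv"))
  invisible(sim)
}

#' @keywords internal
write_manifest <- function(out_dir, config, seed, files) {
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  jsonlite::write_json(
    list(
      package = "peertrends",
      version = as.character(utils::packageVersion("peertrends")),
      seed = seed,
      config = unclass(config),
      digests = as.list(digests)
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(NULL)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `trend` and `compare` subcommands used by the
#' `exec/peertrends` script. Flags: `--config <yaml>`, `--seed <int>`,
#' `--corpus <jsonl>`, `--scores <csv>`, `--emotion <name>`,
#' `--out <dir>`, `--quiet`. Exit status: 0 on success, 1 on runtime
#' error, 2 on usage error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: peertrends <simulate|trend|compare> [options]",
    "  simulate --out DIR [--config FILE.yaml] [--seed N]",
    "  trend    --corpus FILE.jsonl --scores FILE.csv --emotion NAME --out DIR",
    "           [--seed N] [--quiet]",
    "  compare  --corpus FILE.jsonl --scores FILE.csv --emotion NAME --out DIR",
    "           [--seed N] [--quiet]",
    sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1]
  opts <- list(seed = 1L, quiet = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") {
      opts$quiet <- TRUE
      i <- i + 1L
      next
    }
    if (!startsWith(a, "--") || i + 1L > length(args)) {
      message("unexpected argument: ", a, "\n", usage)
      return(invisible(2L))
    }
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts$seed <- as.integer(opts$seed)
  run <- function(expr) {
    tryCatch({
      expr
      0L
    }, ptr_empty_filter_error = function(e) {
      message("diagnostic: ", conditionMessage(e))
      1L
    }, error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    })
  }
  status <- switch(cmd,
    simulate = {
      if (is.null(opts$out)) {
        message("simulate requires --out\n", usage)
        return(invisible(2L))
      }
      cfg_overrides <- if (!is.null(opts$config)) {
        if (!file.exists(opts$config)) {
          message("missing config file: ", opts$config, "\n", usage)
          return(invisible(2L))
        }
        yaml::read_yaml(opts$config)
      } else list()
      run(run_simulate(do.call(generator_config, cfg_overrides),
                       seed = opts$seed, out_dir = opts$out))
    },
    trend = ,
    compare = {
      need <- c("corpus", "scores", "emotion", "out")
      miss <- need[vapply(need, function(k) is.null(opts[[k]]), logical(1))]
      if (length(miss)) {
        message(cmd, " requires --", paste(miss, collapse = " --"), "\n",
                usage)
        return(invisible(2L))
      }
      if (cmd == "trend") {
        run(run_trend(opts$corpus, opts$scores, opts$emotion,
                      out_dir = opts$out, quiet = opts$quiet))
      } else {
        run(run_compare(opts$corpus, opts$scores, opts$emotion,
                        seed = opts$seed, out_dir = opts$out,
                        quiet = opts$quiet))
      }
    },
    {
      message("unknown subcommand: ", cmd, "\n", usage)
      2L
    }
  )
  invisible(status)
}
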