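#' Split user chat sessions into single-user and small-group cohorts
#'
#' A room belongs to the moderator+small-group cohort when its transcript
#' contains at least `group_min_users` distinct non-moderator authors
#' (default 2), and to the moderator+single-user cohort when it contains
#' exactly one. Every user chat session inherits its room's cohort. Rooms
#' whose transcript contains no user-authored message cannot be labeled and
#' are excluded with a warning.
#'
#' @param corpus A [chat_corpus()].
#' @param group_min_users Minimum distinct users for the group cohort.
#' @return The corpus' `sessions` tibble with an added `cohort` column
#'   (`"single"` / `"group"`), excluded rooms dropped.
#' @export
split_cohorts <- function(corpus, group_min_users = 2L) {
  stopifnot(inherits(corpus, "chat_corpus"))
  tr <- corpus$transcripts
  users_by_room <- tapply(
    tr$author_id[tr$author_role == "user"],
    tr$session_key[tr$author_role == "user"],
    function(a) length(unique(a))
  )
  s <- corpus$sessions
  n_users <- as.vector(users_by_room[s$session_key])
  silent <- is.na(n_users) | n_users == 0
  if (any(silent)) {
    warning(sum(silent), " session(s) in rooms with no user messages were ",
            "excluded from cohort labeling")
  }
  s <- s[!silent, , drop = FALSE]
  n_users <- n_users[!silent]
  s$cohort <- ifelse(n_users >= group_min_users, "group", "single")
  s
}

#' Matching caliper from pooled propensities
#'
#' The caliper is `fraction` (default 25%) of the population SD of the
#' propensity scores of *both* cohorts pooled.
#'
#' @param propensities Numeric vector of all propensity scores (length >= 2).
#' @param fraction Fraction of the pooled SD (default 0.25).
#' @return The caliper radius.
#' @export
compute_caliper <- function(propensities, fraction = 0.25) {
  p <- propensities[!is.na(propensities)]
  if (length(p) < 2L) {
    ptr_error("need at least 2 propensity values for a caliper",
              "ptr_validation_error")
  }
  fraction * sqrt(mean((p - mean(p))^2))
}

#' Greedy caliper-restricted nearest-neighbor matching
#'
#' Pairs each single-cohort session with its nearest group-cohort session by
#' absolute propensity difference, 1:1 and without replacement: single
#' sessions are visited in descending propensity order (ties broken by a
#' seeded random shuffle), and each takes the closest still-unused group
#' session within the caliper. Sessions of either cohort left without a
#' partner are excluded from the matched analysis.
#'
#' @param single,group Data frames with at least `session_key`, `user_id`,
#'   `propensity`.
#' @param caliper Maximum allowed |propensity difference| (see
#'   [compute_caliper()]).
#' @param seed Integer seed for the tie-break shuffle.
#' @return Object of class `match_result`: list with `pairs` (tibble:
#'   single/group keys, propensities, `delta`), `unmatched_single`,
#'   `unmatched_group` (tibbles), `caliper`, `seed`.
#' @export
match_cohorts <- function(single, group, caliper, seed = 1L) {
  if (!nrow(single) || !nrow(group)) {
    ptr_error("both cohorts must be non-empty", "ptr_validation_error")
  }
  ps <- single$propensity
  pg <- group$propensity
  ord <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    shuffle <- sample.int(length(ps))
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    order(-ps, shuffle)
  })
  avail <- rep(TRUE, length(pg))
  si <- gi <- integer(0)
  for (i in ord) {
    d <- abs(pg - ps[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= caliper + 1e-12) {
      si <- c(si, i)
      gi <- c(gi, j)
      avail[j] <- FALSE
    }
  }
  pairs <- tibble::tibble(
    single_session_key = single$session_key[si],
    single_user_id = single$user_id[si],
    group_session_key = group$session_key[gi],
    group_user_id = group$user_id[gi],
    propensity_single = ps[si],
    propensity_group = pg[gi],
    delta = abs(ps[si] - pg[gi])
  )
  structure(list(
    pairs = pairs,
    unmatched_single = single[setdiff(seq_len(nrow(single)), si), ,
                              drop = FALSE],
    unmatched_group = group[setdiff(seq_len(nrow(group)), gi), ,
                            drop = FALSE],
    caliper = caliper,
    seed = seed
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs (caliper %.4g); %d single / %d group unmatched\n",
    nrow(x$pairs), x$caliper, nrow(x$unmatched_single),
    nrow(x$unmatched_group)))
  invisible(x)
}

#' Standardized mean differences before and after matching
#'
#' For each feature column, the standardized mean difference between the
#' group and single cohorts, `(mean_g - mean_s) / sqrt((var_g + var_s)/2)`,
#' computed on all sessions (`before`) and on the matched sessions only
#' (`after`). A zero pooled variance yields an SMD of 0.
#'
#' @param features Feature matrix for all sessions (rows aligned with
#'   `labels`).
#' @param labels 0/1 vector (1 = group).
#' @param matched_rows Integer row indices of the matched sessions.
#' @return Tibble with `feature`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(features, labels, matched_rows) {
  smd <- function(x, y) {
    m1 <- mean(x[y == 1])
    m0 <- mean(x[y == 0])
    v <- (stats::var(x[y == 1]) + stats::var(x[y == 0])) / 2
    if (!is.finite(v) || v <= 0) return(0)
    (m1 - m0) / sqrt(v)
  }
  features <- as.matrix(features)
  before <- apply(features, 2, smd, y = labels)
  after <- apply(features[matched_rows, , drop = FALSE], 2, smd,
                 y = labels[matched_rows])
  tibble::tibble(feature = colnames(features),
                 smd_before = unname(before),
                 smd_after = unname(after))
}

#' Propensity-match the two cohorts of a corpus
#'
#' Runs the full matching stage for one emotion: cohort split, propensity
#' features (topic, device, and the struggle's initial intensity on that
#' emotion's reporting scale), ridge-stabilized logistic fit, caliper from
#' the pooled propensity SD, greedy nearest-neighbor matching, and balance
#' diagnostics. Matching is performed independently per emotion and on all
#' sessions with at least one message; emotion-specific inclusion filters
#' are applied afterwards, inside each matched cohort.
#'
#' @param corpus A [chat_corpus()].
#' @param scores Score replay table (raw scale; must contain the t = 0
#'   struggle rows).
#' @param emotion An [emotion_spec()] or emotion name.
#' @param caliper_fraction Fraction of pooled propensity SD (default 0.25).
#' @param group_min_users See [split_cohorts()].
#' @param seed Tie-break seed for [match_cohorts()].
#' @return A `match_result` with extra fields `model`, `balance`,
#'   `sessions` (the labeled sessions with propensities) and `emotion`.
#' @export
propensity_match <- function(corpus, scores, emotion,
                             caliper_fraction = 0.25,
                             group_min_users = 2L, seed = 1L) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  sessions <- split_cohorts(corpus, group_min_users = group_min_users)
  sessions <- sessions[sessions$message_count >= 1L, , drop = FALSE]
  if (!nrow(sessions)) {
    ptr_error("no sessions with messages to match", "ptr_validation_error")
  }
  s0 <- struggle_scores(scores, emotion$name)
  key <- paste(sessions$session_key, sessions$user_id, sep = "\r")
  raw0 <- s0$value[match(key, paste(s0$session_key, s0$user_id, sep = "\r"))]
  if (anyNA(raw0)) {
    ptr_error("missing struggle scores for some sessions",
              "ptr_validation_error")
  }
  sessions$initial_intensity <- emotion$to_reporting(raw0)
  sessions$struggle_raw <- raw0
  feats <- session_features(sessions$topic, sessions$device,
                            sessions$initial_intensity)
  y <- as.numeric(sessions$cohort == "group")
  if (!any(y == 1) || !any(y == 0)) {
    ptr_error("one cohort is empty; cannot match", "ptr_validation_error")
  }
  model <- suppressWarnings(fit_propensity(feats, y))
  sessions$propensity <- predict_propensity(model, feats)
  caliper <- compute_caliper(sessions$propensity,
                             fraction = caliper_fraction)
  res <- match_cohorts(sessions[sessions$cohort == "single", , drop = FALSE],
                       sessions[sessions$cohort == "group", , drop = FALSE],
                       caliper, seed = seed)
  matched_keys <- c(
    paste(res$pairs$single_session_key, res$pairs$single_user_id, sep = "\r"),
    paste(res$pairs$group_session_key, res$pairs$group_user_id, sep = "\r")
  )
  res$model <- model
  res$balance <- balance_table(feats, y, match(matched_keys, key))
  res$sessions <- sessions
  res$emotion <- emotion$name
  res
}

#' Struggle scores (t = 0 rows) from a score table
#' @keywords internal
struggle_scores <- function(scores, emotion_name) {
  s0 <- scores[scores$emotion == emotion_name & scores$t_min == 0, ,
               drop = FALSE]
  s0[!duplicated(paste(s0$session_key, s0$user_id, sep = "\r")), ,
     drop = FALSE]
}

#' Compare the matched cohorts' emotion trends
#'
#' Builds the aggregate trend of each matched cohort (after applying the
#' emotion's inclusion filter within each cohort) and tests, minute by
#' minute, whether the group cohort outperforms the single cohort with a
#' one-sided Mann-Whitney U test in the emotion's improvement direction.
#' The divergence minute is the smallest grid minute from which the
#' between-cohort test stays below `alpha` through the end of the grid.
#'
#' @param match A result of [propensity_match()].
#' @param scores Score replay table (raw scale).
#' @param emotion An [emotion_spec()] or emotion name.
#' @param reference_minute Reference for the per-cohort trends (default 5).
#' @param alpha Significance level (default 0.05).
#' @param grid_max Last grid minute (default 68).
#' @return List with `trend_single`, `trend_group`, `between_p` (tibble
#'   minute / p_value), `divergence_minute` (`NA` if none), `n_single`,
#'   `n_group`.
#' @export
compare_cohorts <- function(match, scores, emotion, reference_minute = 5,
                            alpha = 0.05, grid_max = 68) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  if (nrow(match$pairs) < 2L) {
    ptr_error("need at least 2 matched pairs", "ptr_validation_error")
  }
  sess <- match$sessions
  skey <- paste(sess$session_key, sess$user_id, sep = "\r")
  side <- function(keys) {
    rows <- sess[match(keys, skey), , drop = FALSE]
    keep <- include_session(emotion, rows$struggle_raw, rows$message_count)
    rows <- rows[keep, , drop = FALSE]
    if (nrow(rows) < 2L) {
      ptr_error(paste0("cohort emptied by the ", emotion$name,
                       " inclusion filter"), "ptr_validation_error")
    }
    trajectory_matrix(scores, rows$session_key, rows$user_id, emotion,
                      grid_max = grid_max)
  }
  traj_s <- side(paste(match$pairs$single_session_key,
                       match$pairs$single_user_id, sep = "\r"))
  traj_g <- side(paste(match$pairs$group_session_key,
                       match$pairs$group_user_id, sep = "\r"))
  trend_s <- aggregate_trend(traj_s, emotion,
                             reference_minute = reference_minute)
  trend_g <- aggregate_trend(traj_g, emotion,
                             reference_minute = reference_minute)
  alternative <- if (emotion$improvement_direction == "decrease")
    "less" else "greater"
  minutes <- as.numeric(colnames(traj_s))
  p <- vapply(seq_along(minutes), function(j) {
    mann_whitney_one_sided(traj_g[, j], traj_s[, j], alternative)$p
  }, numeric(1))
  ok <- p < alpha
  run <- rev(cumprod(rev(ok)))
  hit <- which(run == 1)
  divergence <- if (length(hit)) minutes[hit[1]] else NA_real_
  list(
    trend_single = trend_s,
    trend_group = trend_g,
    between_p = tibble::tibble(minute = minutes, p_value = p),
    divergence_minute = divergence,
    n_single = nrow(traj_s),
    n_group = nrow(traj_g)
  )
}

#' Gridded trajectory matrix for a set of user chat sessions
#'
#' Builds one gridded reporting-scale trajectory per (session_key, user_id)
#' from a raw-scale score table: same-time scores are averaged, raw values
#' mapped to the reporting scale, then gridded with [grid_trajectory()].
#'
#' @param scores Score replay table (raw scale).
#' @param session_keys,user_ids Parallel vectors of sessions to include.
#' @param emotion An [emotion_spec()] or emotion name.
#' @param grid_max Last grid minute.
#' @return Numeric matrix, rows = sessions (named `session_key\\ruser_id`),
#'   columns = grid minutes.
#' @export
trajectory_matrix <- function(scores, session_keys, user_ids, emotion,
                              grid_max = 68) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  sc <- scores[scores$emotion == emotion$name, , drop = FALSE]
  sc_key <- paste(sc$session_key, sc$user_id, sep = "\r")
  want <- paste(session_keys, user_ids, sep = "\r")
  parts <- split(seq_len(nrow(sc)), sc_key)
  out <- matrix(NA_real_, nrow = length(want), ncol = grid_max + 1,
                dimnames = list(want, as.character(0:grid_max)))
  for (i in seq_along(want)) {
    rows <- parts[[want[i]]]
    if (is.null(rows)) {
      ptr_error(paste0("no scores for session ", gsub("\r", "/", want[i])),
                "ptr_validation_error")
    }
    t <- sc$t_min[rows]
    v <- emotion$to_reporting(sc$value[rows])
    tu <- sort(unique(t))
    vu <- if (length(tu) == length(t)) v[order(t)] else
      vapply(tu, function(tt) mean(v[t == tt]), numeric(1))
    out[i, ] <- grid_trajectory(list(t_min = tu, value = vu),
                                grid_max = grid_max)
  }
  out
}
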