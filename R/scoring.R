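#' Build per-message scoring contexts for one user
#'
#' Every scored unit is a target text plus the conversational context it is
#' read in. Unit 1 is always the user's struggle, at t = 0, with an empty
#' context. The user's first message in the room is also scored with an
#' empty context. Every later message by the user is scored in the context
#' of all messages by *other* authors (peers and the moderator alike) that
#' fall strictly between the user's previous message and the target message,
#' concatenated in transcript order and separated by single newlines. No
#' author labels are inserted. For the room
#' `[A: m1, B: m2, Mod: m3, A: m4, B: m5]` this scores, for user A, m1 with
#' no context and m4 in the context `m2 + m3`; for user B, m2 with no
#' context and m5 in the context `m3 + m4`.
#'
#' @param session A [user_session()].
#' @return Tibble with one row per unit: `unit` (1-based index), `t_min`,
#'   `is_struggle`, `target_text`, `context_text` (empty string when there
#'   is no context).
#' @export
build_units <- function(session) {
  stopifnot(inherits(session, "user_chat_session"))
  tr <- session$transcript
  if (nrow(tr) && is.unsorted(tr$t_min)) {
    tr <- tr[order(tr$t_min), , drop = FALSE]
  }
  if (is.na(session$struggle_text) || !nzchar(session$struggle_text)) {
    own <- which(tr$author_id == session$user_id)
    if (!length(own)) {
      ptr_error(paste0("user ", session$user_id,
                       " has no struggle and no messages"),
                "ptr_validation_error")
    }
  }
  own <- which(tr$author_id == session$user_id)
  n_units <- 1L + length(own)
  t_min <- numeric(n_units)
  target <- character(n_units)
  context <- character(n_units)
  is_struggle <- c(TRUE, rep(FALSE, length(own)))
  t_min[1] <- 0
  target[1] <- session$struggle_text
  context[1] <- ""
  for (k in seq_along(own)) {
    i <- own[k]
    t_min[k + 1L] <- tr$t_min[i]
    target[k + 1L] <- tr$text[i]
    if (k == 1L) {
      context[k + 1L] <- ""
    } else {
      lo <- own[k - 1L] + 1L
      hi <- i - 1L
      between <- if (lo > hi) integer(0) else seq.int(lo, hi)
      others <- between[tr$author_id[between] != session$user_id]
      context[k + 1L] <- paste(tr$text[others], collapse = "\n")
    }
  }
  tibble::tibble(
    unit = seq_len(n_units),
    t_min = t_min,
    is_struggle = is_struggle,
    target_text = target,
    context_text = context
  )
}

#' Score one user chat session
#'
#' Applies a scorer to every unit from [build_units()] and assembles the
#' resulting score series on the emotion's raw scale (loneliness 1-10;
#' optimism -1/0/+1). Multiple units at the same time are averaged into a
#' single point, so times are strictly increasing. Values outside the raw
#' scale (beyond numerical tolerance) raise an error identifying the unit;
#' in-range values are clamped to the scale bounds.
#'
#' @param session A [user_session()].
#' @param scorer A scorer function `function(unit, emotion)` returning one
#'   numeric value on the emotion's raw scale; see [scorer_replay()] and
#'   [scorer_synthetic()].
#' @param emotion An [emotion_spec()] or emotion name.
#' @return Tibble of class `score_series` with columns `t_min`, `value`
#'   (raw scale) and attributes `session_key`, `user_id`, `emotion`.
#' @export
score_session <- function(session, scorer, emotion) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  units <- build_units(session)
  vals <- numeric(nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- as.list(units[i, ])
    u$session_key <- session$session_key
    u$user_id <- session$user_id
    v <- scorer(u, emotion$name)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      ptr_error(sprintf("scorer returned a non-finite value for unit %d (t=%g) of user %s",
                        i, units$t_min[i], session$user_id),
                "ptr_scorer_error")
    }
    tol <- 1e-8
    if (v < emotion$raw_range[1] - tol || v > emotion$raw_range[2] + tol) {
      ptr_error(sprintf(
        "scorer returned %g, outside the %s raw scale [%g, %g], for unit %d (t=%g) of user %s",
        v, emotion$name, emotion$raw_range[1], emotion$raw_range[2],
        i, units$t_min[i], session$user_id), "ptr_scorer_error")
    }
    vals[i] <- min(max(v, emotion$raw_range[1]), emotion$raw_range[2])
  }
  t_avg <- sort(unique(units$t_min))
  v_avg <- vapply(t_avg, function(t) mean(vals[units$t_min == t]),
                  numeric(1))
  structure(
    tibble::tibble(t_min = t_avg, value = v_avg),
    session_key = session$session_key,
    user_id = session$user_id,
    emotion = emotion$name,
    class = c("score_series", class(tibble::tibble()))
  )
}

#' Replay scorer
#'
#' A scorer that looks each unit up in a precomputed score table (the
#' mechanism used both to replay external model scores and to feed the
#' synthetic generator's scores through the scoring pipeline). The unit's
#' `(session_key, user_id, emotion, t_min)` must match a table row (times
#' within 1e-6 minutes); a missing row is an error.
#'
#' @param scores Score table as from [read_score_table()].
#' @return A scorer function for [score_session()].
#' @export
scorer_replay <- function(scores) {
  idx <- split(
    scores[c("t_min", "value")],
    paste(scores$session_key, scores$user_id, scores$emotion, sep = "\r")
  )
  function(unit, emotion) {
    rows <- idx[[paste(unit$session_key, unit$user_id, emotion, sep = "\r")]]
    if (is.null(rows)) {
      ptr_error(sprintf("no replay scores for (%s, %s, %s)",
                        unit$session_key, unit$user_id, emotion),
                "ptr_scorer_error")
    }
    d <- abs(rows$t_min - unit$t_min)
    j <- which.min(d)
    if (!length(j) || d[j] > 1e-6) {
      ptr_error(sprintf("no replay score at t=%g for (%s, %s, %s)",
                        unit$t_min, unit$session_key, unit$user_id, emotion),
                "ptr_scorer_error")
    }
    mean(rows$value[abs(rows$t_min - rows$t_min[j]) <= 1e-9])
  }
}

#' Synthetic scorer
#'
#' Scores units from a synthetic corpus using the generator's latent
#' trajectories (see [generate_corpus()]). With `sigma_obs = 0` it returns
#' the latent value discretized to the emotion's raw scale, so the series
#' equals the discretized latent trajectory exactly; with noise it is still
#' deterministic for a given `seed` and call sequence.
#'
#' @param truth The `truth` component of a [generate_corpus()] result.
#' @param sigma_obs Observation noise SD on the loneliness scale (and the
#'   logistic dispersion used for optimism); default 0.
#' @param seed Integer seed for the scorer's private noise stream.
#' @return A scorer function for [score_session()].
#' @export
scorer_synthetic <- function(truth, sigma_obs = 0, seed = 1L) {
  par <- truth$params
  key <- paste(par$session_key, par$user_id, sep = "\r")
  rng <- new.env(parent = emptyenv())
  rng$state <- NULL
  draw <- function(fn) {
    # draw from a private RNG stream without disturbing the caller's RNG
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(rng$state)) set.seed(seed) else
      assign(".Random.seed", rng$state, envir = globalenv())
    z <- fn()
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    z
  }
  function(unit, emotion) {
    i <- match(paste(unit$session_key, unit$user_id, sep = "\r"), key)
    if (is.na(i)) {
      ptr_error(sprintf("no ground truth for (%s, %s)",
                        unit$session_key, unit$user_id), "ptr_scorer_error")
    }
    t <- min(unit$t_min, par$duration_min[i])
    if (emotion == "loneliness") {
      L <- latent_loneliness(t, par$l0[i], par$l_end[i], par$decay_rate[i],
                             par$t_lag[i])
      eps <- if (sigma_obs > 0) sigma_obs * draw(function() stats::rnorm(1))
             else 0
      min(max(round(L + eps), 1), 10)
    } else {
      O <- latent_optimism(t, par$o0[i], par$o_end[i], par$rise_rate[i],
                           par$rise_mid[i])
      u <- if (sigma_obs > 0) draw(function() stats::runif(1)) else NULL
      observe_optimism_raw(O, sigma_obs, u)
    }
  }
}

#' Few-shot anchor examples for the emotion scorers
#'
#' Loads the packaged anchor texts and labels used to calibrate an external
#' text-scoring model: loneliness anchors at intensities 1 (low), 5
#' (moderate) and 10 (high), and optimism anchors at +1 (positive), 0
#' (neutral) and -1 (negative).
#'
#' @param path Path to the anchor fixture; defaults to the copy installed
#'   with the package.
#' @return Named list with elements `loneliness` and `optimism`, each a data
#'   frame with columns `label` and `text`.
#' @export
fewshot_anchors <- function(path = system.file("extdata",
                                               "fewshot_anchors.json",
                                               package = "peertrends")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    ptr_error("few-shot anchor fixture not found", "ptr_config_error")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Assemble a scoring prompt
#'
#' Builds the byte-stable prompt an external scoring model would receive for
#' one unit: a task instruction, the few-shot anchors verbatim, then the
#' unit's context and target text. The package never calls such a model
#' itself; this is the documented adapter surface.
#'
#' @param emotion `"loneliness"` or `"optimism"`.
#' @param unit One row of [build_units()] output (as a list or 1-row tibble).
#' @param anchors Anchor fixture from [fewshot_anchors()].
#' @return A single prompt string.
#' @export
assemble_prompt <- function(emotion = c("loneliness", "optimism"), unit,
                            anchors = fewshot_anchors()) {
  emotion <- match.arg(emotion)
  if (is.null(anchors[[emotion]])) {
    ptr_error("anchor fixture has no entry for this emotion",
              "ptr_config_error")
  }
  a <- anchors[[emotion]]
  head <- if (emotion == "loneliness") {
    "Rate the loneliness expressed in the message on a scale of 1 to 10 (1=low, 5=moderate, 10=high intensity)."
  } else {
    "Rate the optimism expressed in the message as -1 (negative), 0 (neutral) or +1 (positive)."
  }
  shots <- paste(sprintf("%s: \"%s\"", a$label, a$text), collapse = "\n")
  ctx <- if (nzchar(unit$context_text)) unit$context_text else "(none)"
  paste0(head, "\n\nExamples:\n", shots,
         "\n\nContext:\n", ctx,
         "\n\nMessage:\n", unit$target_text, "\n")
}
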