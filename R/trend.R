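#' Session inclusion rule for a trend
#'
#' A session contributes to an emotion's aggregate trend only if its user
#' sent at least one message (a struggle alone carries no trajectory). For
#' loneliness the session must additionally open with at least moderate
#' loneliness: the struggle's raw score must be *strictly* greater than 5.
#' All sessions with messages are included for optimism.
#'
#' @param emotion An [emotion_spec()] or emotion name.
#' @param struggle_score Raw-scale struggle score(s); ignored for optimism.
#' @param message_count Number of messages the user sent.
#' @return Logical vector.
#' @export
include_session <- function(emotion, struggle_score, message_count) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  has_msgs <- !is.na(message_count) & message_count >= 1L
  if (is.na(emotion$inclusion_threshold)) {
    has_msgs
  } else {
    has_msgs & !is.na(struggle_score) &
      struggle_score > emotion$inclusion_threshold
  }
}

#' Grid a score series onto the minute grid
#'
#' Places a user's (time, value) points on the regular grid `0, step, ...,
#' grid_max` minutes (default 0..68, 69 entries) by piecewise-linear
#' interpolation between observed points, with constant extrapolation
#' outside the observed range (first value carried backward, last value
#' carried forward). Observed points that fall on grid minutes are
#' reproduced exactly.
#'
#' @param series A `score_series` (or any data frame with `t_min`, `value`),
#'   with values already on the scale to be gridded.
#' @param grid_max Last grid minute (default 68).
#' @param step Grid step in minutes (default 1).
#' @return Numeric vector of length `grid_max / step + 1`, named by minute.
#' @export
grid_trajectory <- function(series, grid_max = 68, step = 1) {
  t <- series$t_min
  v <- series$value
  if (!length(t)) {
    ptr_error("cannot grid an empty score series", "ptr_validation_error")
  }
  grid <- seq(0, grid_max, by = step)
  out <- if (length(unique(t)) == 1L) {
    rep(mean(v), length(grid))
  } else {
    stats::approx(t, v, xout = grid, method = "linear", rule = 2,
                  ties = mean)$y
  }
  names(out) <- as.character(grid)
  out
}

#' Aggregate user trajectories into an emotion trend
#'
#' Combines the gridded trajectories of all included users into the
#' aggregate trend: per-minute mean, population SD and n across users, plus
#' a one-sided Mann-Whitney p-value comparing the cross-user sample at each
#' minute with the sample at the reference minute (default 5), in the
#' emotion's improvement direction (loneliness: decrease; optimism:
#' increase). The p-value at the reference minute itself is `NA`.
#'
#' @param traj Numeric matrix, one row per user trajectory, columns = grid
#'   minutes (as from [grid_trajectory()], values on the reporting scale).
#' @param emotion An [emotion_spec()] or emotion name.
#' @param reference_minute Reference grid minute (default 5).
#' @param alternative Override for the test direction; defaults to the
#'   emotion's improvement direction.
#' @return Tibble with columns `minute`, `mean`, `sd`, `n`, `p_value`, and
#'   attributes `emotion` and `reference_minute`.
#' @export
aggregate_trend <- function(traj, emotion, reference_minute = 5,
                            alternative = NULL) {
  if (is.character(emotion)) emotion <- emotion_spec(emotion)
  if (is.list(traj) && !is.matrix(traj) && !is.data.frame(traj)) {
    emos <- unique(vapply(traj, function(s) attr(s, "emotion") %||% emotion$name,
                          character(1)))
    if (length(emos) > 1L) {
      ptr_error("trajectories mix emotions", "ptr_validation_error")
    }
    if (all(vapply(traj, is.data.frame, logical(1)))) {
      traj <- lapply(traj, function(s) {
        s$value <- emotion$to_reporting(s$value)
        grid_trajectory(s)
      })
    }
    traj <- do.call(rbind, traj)
  }
  if (!is.matrix(traj) || nrow(traj) < 2L) {
    ptr_error("need at least 2 trajectories to aggregate",
              "ptr_validation_error")
  }
  minutes <- as.numeric(colnames(traj))
  ref_col <- match(reference_minute, minutes)
  if (is.na(ref_col)) {
    ptr_error("reference minute is not on the grid", "ptr_validation_error")
  }
  if (is.null(alternative)) {
    alternative <- if (emotion$improvement_direction == "decrease")
      "less" else "greater"
  }
  n <- nrow(traj)
  mu <- colMeans(traj)
  sdv <- sqrt(colMeans(traj^2) - mu^2)
  sdv[sdv < 0] <- 0
  ref <- traj[, ref_col]
  p <- rep(NA_real_, ncol(traj))
  for (j in seq_len(ncol(traj))) {
    if (j == ref_col) next
    p[j] <- mann_whitney_one_sided(traj[, j], ref, alternative)$p
  }
  structure(
    tibble::tibble(minute = minutes, mean = unname(mu), sd = unname(sdv),
                   n = n, p_value = p),
    emotion = emotion$name,
    reference_minute = reference_minute,
    alternative = alternative,
    class = c("aggregate_trend", class(tibble::tibble()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the significance onset of a trend
#'
#' The onset is the earliest post-reference grid minute from which the
#' one-sided test against the reference stays below `alpha` at *every*
#' minute through the end of the grid ("consistently significant"). Returns
#' `NA` when no such minute exists.
#'
#' @param trend An [aggregate_trend()].
#' @param alpha Significance level (default 0.05).
#' @return Onset minute, or `NA_real_`.
#' @export
detect_onset <- function(trend, alpha = 0.05) {
  ref <- attr(trend, "reference_minute")
  post <- which(trend$minute > ref)
  if (!length(post)) return(NA_real_)
  ok <- !is.na(trend$p_value[post]) & trend$p_value[post] < alpha
  # longest suffix of post-reference minutes that is entirely significant
  run <- rev(cumprod(rev(ok)))
  hit <- which(run == 1)
  if (!length(hit)) return(NA_real_)
  trend$minute[post[hit[1]]]
}

#' Percent change of a trend relative to its reference
#'
#' Computes the percentage change of the aggregate mean at time `t`
#' (fractional minutes allowed; the mean curve is linearly interpolated)
#' against the reference mean. The magnitude is
#' \code{100 * |mean(t) - mean(ref)| / denom} and the sign is positive when
#' the change goes in the emotion's improvement direction (a drop for
#' loneliness, a rise for optimism). `denom` is the reference mean for mode
#' `"relative_to_reference"` (the default), the mean at the last grid
#' minute for `"relative_to_end"`, and the range of the mean curve for
#' `"relative_to_range"`.
#'
#' @param trend An [aggregate_trend()].
#' @param t Time in minutes within the grid.
#' @param mode Denominator convention, see above.
#' @return Signed percent change.
#' @export
percent_change <- function(trend, t,
                           mode = c("relative_to_reference",
                                    "relative_to_end",
                                    "relative_to_range")) {
  mode <- match.arg(mode)
  ref <- attr(trend, "reference_minute")
  improvement <- attr(trend, "alternative")
  m_t <- stats::approx(trend$minute, trend$mean, xout = t, rule = 2)$y
  m_ref <- trend$mean[match(ref, trend$minute)]
  denom <- switch(mode,
    relative_to_reference = m_ref,
    relative_to_end = trend$mean[nrow(trend)],
    relative_to_range = diff(range(trend$mean))
  )
  if (!is.finite(denom) || denom == 0) {
    ptr_error("percent change denominator is zero", "ptr_validation_error")
  }
  delta <- m_t - m_ref
  signed <- if (improvement == "less") -delta else delta
  100 * sign(signed) * abs(delta) / denom
}

#' Summarize an aggregate trend
#'
#' Start/end means and SDs, percent changes at the end of the grid and at an
#' intermediate time (default 19.4 minutes, a typical average session
#' duration), the significance onset, and n.
#'
#' @param trend An [aggregate_trend()].
#' @param at Intermediate time for the second percent change (minutes).
#' @param alpha Significance level for the onset.
#' @param mode Percent-change mode, see [percent_change()].
#' @return Named list.
#' @export
trend_summary <- function(trend, at = 19.4, alpha = 0.05,
                          mode = "relative_to_reference") {
  ref <- attr(trend, "reference_minute")
  i_ref <- match(ref, trend$minute)
  i_end <- nrow(trend)
  onset <- detect_onset(trend, alpha = alpha)
  p_end <- trend$p_value[i_end]
  list(
    emotion = attr(trend, "emotion"),
    n = trend$n[1],
    reference_minute = ref,
    start_value = trend$mean[i_ref],
    sd_start = trend$sd[i_ref],
    end_value = trend$mean[i_end],
    sd_end = trend$sd[i_end],
    pct_change_at_end = percent_change(trend, trend$minute[i_end],
                                       mode = mode),
    pct_change_at = stats::setNames(percent_change(trend, at, mode = mode),
                                    format(at)),
    onset_minute = onset,
    p_value_at_end = p_end
  )
}
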