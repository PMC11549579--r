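#' Latent loneliness trajectory
#'
#' Exponential approach from a starting intensity `l0` (at least moderate)
#' toward an asymptote `l_end`, with no change before the lag:
#' `L(t) = l_end + (l0 - l_end) * exp(-rate * max(0, t - t_lag))`,
#' clamped to the 1-10 scale.
#'
#' @param t Time(s) in minutes.
#' @param l0 Starting intensity.
#' @param l_end Asymptotic intensity.
#' @param rate Decay rate per minute (> 0).
#' @param t_lag Minutes before the decay starts.
#' @return Latent intensity values in [1, 10].
#' @export
latent_loneliness <- function(t, l0, l_end, rate, t_lag = 0) {
  L <- l_end + (l0 - l_end) * exp(-rate * pmax(t - t_lag, 0))
  pmin(pmax(L, 1), 10)
}

#' Latent optimism trajectory
#'
#' Logistic rise on [0, 1] from `o0` toward `o_end`, normalized so the
#' curve starts exactly at `o0` at t = 0:
#' `O(t) = o0 + (o_end - o0) * s(t)` with
#' `s(t) = (plogis(rate * (t - mid)) - plogis(-rate * mid)) /
#' (1 - plogis(-rate * mid))`.
#'
#' @param t Time(s) in minutes.
#' @param o0 Starting value in [0, 1].
#' @param o_end Asymptotic value in [0, 1].
#' @param rate Rise rate per minute (> 0).
#' @param mid Inflection minute of the logistic rise.
#' @return Latent values in [0, 1].
#' @export
latent_optimism <- function(t, o0, o_end, rate, mid = 12) {
  base <- stats::plogis(-rate * mid)
  s <- (stats::plogis(rate * (t - mid)) - base) / (1 - base)
  pmin(pmax(o0 + (o_end - o0) * s, 0), 1)
}

#' Observe a raw optimism valence from the latent value
#'
#' Ordered-logit observation model: with dispersion `s`, the valence is -1
#' with probability `plogis((0.35 - O)/s)`, at most 0 with probability
#' `plogis((0.65 - O)/s)`, else +1. With `s = 0` the thresholds are hard:
#' -1 below 0.35, 0 up to 0.65, +1 above.
#'
#' @param O Latent optimism in [0, 1].
#' @param s Logistic dispersion (0 = deterministic thresholds).
#' @param u Uniform(0,1) draw used when `s > 0` (vectorized with `O`).
#' @return Raw valences in \{-1, 0, 1\}.
#' @export
observe_optimism_raw <- function(O, s, u = NULL) {
  if (is.null(s) || s <= 0) {
    ifelse(O < 0.35, -1, ifelse(O <= 0.65, 0, 1))
  } else {
    p_neg <- stats::plogis((0.35 - O) / s)
    p_le0 <- stats::plogis((0.65 - O) / s)
    ifelse(u < p_neg, -1, ifelse(u < p_le0, 0, 1))
  }
}

#' Configuration for the synthetic chat-corpus generator
#'
#' Defaults emulate the corpus the pipeline is designed for: 699 user chat
#' rooms with lognormal durations (mean about 19.4 minutes, 95th percentile
#' about 68, capped at 262), topics and devices drawn with the observed
#' frequencies, 30 percent of users dropping off without sending a message,
#' latent loneliness starting at least moderate and decaying exponentially,
#' and latent optimism rising logistically. `group_rate_multiplier`
#' multiplies the decay/rise rates of users in small-group rooms, encoding
#' a configurable peer effect (1 = no effect).
#'
#' @param n_sessions Number of rooms.
#' @param group_fraction Fraction of rooms with 2-4 users (the rest have 1).
#' @param users_per_group_weights Sampling weights for 2, 3, 4 users.
#' @param duration_meanlog,duration_sdlog Lognormal duration parameters
#'   (defaults solve mean 19.4 / 95th pct 68).
#' @param duration_cap Upper cap on durations, minutes.
#' @param message_rate Per-user message rate, messages/minute.
#' @param moderator_rate Moderator message rate, messages/minute.
#' @param zero_message_fraction Expected fraction of users who never send a
#'   message (they still submit a struggle).
#' @param dropout_tau Duration scale (minutes) of the zero-message dropout.
#'   Silent users are the short sessions: with the default `0`, users never
#'   message exactly when their room is shorter than the
#'   `zero_message_fraction` quantile of the duration distribution (a hard
#'   threshold, which keeps the dropout mechanism identical for both
#'   cohorts); with `dropout_tau > 0` the probability of never messaging
#'   decays smoothly as `exp(-duration / dropout_tau)`, rescaled so its
#'   mean equals `zero_message_fraction`.
#' @param l0_mean,l0_sd,l0_min,l0_max Truncated-normal starting loneliness.
#' @param l_end Loneliness asymptote.
#' @param decay_rate Loneliness decay rate per minute.
#' @param t_lag Minutes before the loneliness decay (and optimism rise)
#'   starts; a lag beyond the grid yields a flat (null) corpus.
#' @param sigma_obs Observation noise SD on the loneliness scale.
#' @param o0_mean,o0_sd Starting optimism (normal, clamped to [0, 0.6]).
#' @param o_end Optimism asymptote.
#' @param rise_rate Optimism rise rate per minute.
#' @param rise_mid Optimism inflection minute.
#' @param sigma_obs_optimism Ordered-logit dispersion for optimism.
#' @param group_rate_multiplier Rate multiplier for group-room users.
#' @param topic_weights,device_weights Named categorical weights (must sum
#'   to 1) over [chat_topics] / [chat_devices].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_sessions = 699L,
                             group_fraction = 0.5,
                             users_per_group_weights = c(`2` = 0.6,
                                                         `3` = 0.3,
                                                         `4` = 0.1),
                             duration_meanlog = 2.2417,
                             duration_sdlog = 1.2032,
                             duration_cap = 262,
                             message_rate = 0.5,
                             moderator_rate = 0.7,
                             zero_message_fraction = 0.30,
                             dropout_tau = 0,
                             l0_mean = 6.5, l0_sd = 1.0,
                             l0_min = 5, l0_max = 10,
                             l_end = 2, decay_rate = 0.05, t_lag = 0,
                             sigma_obs = 1,
                             o0_mean = 0.25, o0_sd = 0.08,
                             o_end = 0.80, rise_rate = 0.12, rise_mid = 12,
                             sigma_obs_optimism = 0.12,
                             group_rate_multiplier = 1.0,
                             topic_weights = NULL,
                             device_weights = c(desktop = 0.55,
                                                mobile = 0.42,
                                                tablet = 0.03)) {
  if (is.null(topic_weights)) {
    # observed struggle-topic frequencies (counts out of 489), in the order
    # of chat_topics
    counts <- c(98, 73, 43, 43, 24, 34, 43, 29, 34, 10, 19, 5, 5, 29)
    topic_weights <- stats::setNames(counts / sum(counts), chat_topics)
  }
  cfg <- list(
    n_sessions = as.integer(n_sessions),
    group_fraction = group_fraction,
    users_per_group_weights = users_per_group_weights,
    duration_meanlog = duration_meanlog,
    duration_sdlog = duration_sdlog,
    duration_cap = duration_cap,
    message_rate = message_rate,
    moderator_rate = moderator_rate,
    zero_message_fraction = zero_message_fraction,
    dropout_tau = dropout_tau,
    l0_mean = l0_mean, l0_sd = l0_sd, l0_min = l0_min, l0_max = l0_max,
    l_end = l_end, decay_rate = decay_rate, t_lag = t_lag,
    sigma_obs = sigma_obs,
    o0_mean = o0_mean, o0_sd = o0_sd, o_end = o_end,
    rise_rate = rise_rate, rise_mid = rise_mid,
    sigma_obs_optimism = sigma_obs_optimism,
    group_rate_multiplier = group_rate_multiplier,
    topic_weights = topic_weights,
    device_weights = device_weights
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @keywords internal
validate_generator_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) ptr_error(msg,
                                                          "ptr_config_error")
  chk(cfg$n_sessions >= 1L, "n_sessions must be >= 1")
  chk(cfg$group_fraction >= 0 && cfg$group_fraction <= 1,
      "group_fraction must be in [0, 1]")
  chk(all(names(cfg$users_per_group_weights) %in% c("2", "3", "4")) &&
        all(cfg$users_per_group_weights >= 0) &&
        sum(cfg$users_per_group_weights) > 0,
      "users_per_group_weights must be non-negative weights on 2..4")
  chk(cfg$duration_sdlog > 0 && cfg$duration_cap > 0,
      "duration parameters must be positive")
  chk(cfg$message_rate > 0 && cfg$moderator_rate > 0,
      "message rates must be > 0")
  chk(cfg$zero_message_fraction >= 0 && cfg$zero_message_fraction < 1,
      "zero_message_fraction must be in [0, 1)")
  chk(cfg$dropout_tau >= 0, "dropout_tau must be >= 0")
  chk(cfg$decay_rate > 0 && cfg$rise_rate > 0 &&
        cfg$group_rate_multiplier > 0, "all rates must be > 0")
  chk(cfg$l0_min >= 1 && cfg$l0_max <= 10 && cfg$l0_min < cfg$l0_max,
      "l0 bounds must satisfy 1 <= l0_min < l0_max <= 10")
  chk(cfg$sigma_obs >= 0 && cfg$sigma_obs_optimism >= 0,
      "observation noise must be >= 0")
  chk(abs(sum(cfg$topic_weights) - 1) < 1e-8 &&
        identical(names(cfg$topic_weights), chat_topics),
      "topic_weights must be named by chat_topics and sum to 1")
  chk(abs(sum(cfg$device_weights) - 1) < 1e-8 &&
        identical(names(cfg$device_weights), chat_devices),
      "device_weights must be named by chat_devices and sum to 1")
  invisible(cfg)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @keywords internal
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling of a truncated normal
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic chat corpus with ground truth
#'
#' Simulates rooms, users, message times (a homogeneous Poisson process per
#' author truncated at the room duration), latent emotional trajectories,
#' and noisy observed scores. The result contains everything the pipeline
#' consumes (a [chat_corpus()] and a raw-scale score replay table) plus the
#' exported ground truth: per-user latent parameters, latent trajectories
#' sampled on the minute grid (frozen at the session end, mirroring what is
#' observable), and a noise-free score table for oracle runs. Regenerating
#' with the same config and seed is bit-identical.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with `corpus` (a [chat_corpus()]), `scores` (replay table
#'   tibble), and `truth` (list: `params` tibble, `latent_loneliness` and
#'   `latent_optimism` matrices on minutes 0..68, `scores_noisefree`
#'   tibble, `config`, `seed`).
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  with_seed(seed, generate_corpus_impl(config, seed))
}

#' @keywords internal
generate_corpus_impl <- function(cfg, seed) {
  ns <- cfg$n_sessions
  session_key <- sprintf("S%05d", seq_len(ns))
  duration <- pmin(stats::rlnorm(ns, cfg$duration_meanlog,
                                 cfg$duration_sdlog), cfg$duration_cap)
  is_group <- stats::runif(ns) < cfg$group_fraction
  gw <- cfg$users_per_group_weights / sum(cfg$users_per_group_weights)
  gsizes <- as.integer(names(gw))
  drawn <- if (length(gsizes) == 1L) rep(gsizes, ns) else
    sample(gsizes, ns, replace = TRUE, prob = gw)
  n_users <- ifelse(is_group, drawn, 1L)

  # one row per user chat session
  sk <- rep(session_key, n_users)
  dur <- rep(duration, n_users)
  grp <- rep(is_group, n_users)
  uidx <- sequence(n_users)
  uid <- paste0(sk, "_U", uidx)
  nu <- length(uid)

  topic <- sample(chat_topics, nu, replace = TRUE, prob = cfg$topic_weights)
  device <- sample(chat_devices, nu, replace = TRUE,
                   prob = cfg$device_weights)
  # dropout without messaging is concentrated in short sessions: the
  # per-user probability decays with duration, rescaled so its mean equals
  # the configured zero-message fraction
  zfrac <- cfg$zero_message_fraction
  if (zfrac <= 0) {
    zero_msg <- rep(FALSE, nu)
  } else if (cfg$dropout_tau == 0) {
    d_star <- stats::qlnorm(zfrac, cfg$duration_meanlog, cfg$duration_sdlog)
    zero_msg <- dur < d_star
  } else {
    w <- exp(-dur / cfg$dropout_tau)
    p_zero <- if (all(w <= 0)) rep(zfrac, nu) else {
      f <- function(cc) mean(pmin(1, cc * w)) - zfrac
      cc <- if (f(1e8) <= 0) 1e8 else
        stats::uniroot(f, c(1e-12, 1e8), tol = 1e-10)$root
      pmin(1, cc * w)
    }
    zero_msg <- stats::runif(nu) < p_zero
  }
  l0 <- rtruncnorm1(nu, cfg$l0_mean, cfg$l0_sd, cfg$l0_min, cfg$l0_max)
  o0 <- pmin(pmax(stats::rnorm(nu, cfg$o0_mean, cfg$o0_sd), 0), 0.6)
  # the peer effect acts through peers who actually chat: a user enjoys the
  # group rate multiplier only when >= 2 users of the room send messages,
  # which is also what the analysis-side cohort split observes
  msg_users <- tapply(!zero_msg, sk, sum)
  eff_group <- as.vector(msg_users[sk]) >= 2L
  rate_mult <- ifelse(eff_group, cfg$group_rate_multiplier, 1)

  params <- tibble::tibble(
    session_key = sk, user_id = uid,
    duration_min = dur, is_group_room = eff_group, zero_message = zero_msg,
    topic = topic, device = device,
    l0 = l0, l_end = cfg$l_end,
    decay_rate = cfg$decay_rate * rate_mult, t_lag = cfg$t_lag,
    # the optimism multiplier acts as a time dilation (the same rise is
    # traversed rate_mult times faster), which scales the rate up and the
    # midpoint down while leaving the curve's start value unchanged
    o0 = o0, o_end = cfg$o_end,
    rise_rate = cfg$rise_rate * rate_mult, rise_mid = cfg$rise_mid / rate_mult
  )

  # message times: homogeneous Poisson process per user on [0, duration]
  n_msgs <- ifelse(zero_msg, 0L,
                   pmax(1L, stats::rpois(nu, cfg$message_rate * dur)))
  row_of_msg <- rep(seq_len(nu), n_msgs)
  t_msg <- stats::runif(sum(n_msgs)) * dur[row_of_msg]
  msg_user <- tibble::tibble(
    session_key = sk[row_of_msg],
    author_id = uid[row_of_msg],
    author_role = "user",
    t_min = t_msg,
    text = sprintf("message %d from %s",
                   sequence(n_msgs[n_msgs > 0L]), uid[row_of_msg])
  )
  n_mod <- stats::rpois(ns, cfg$moderator_rate * duration)
  mod_of_msg <- rep(seq_len(ns), n_mod)
  msg_mod <- tibble::tibble(
    session_key = session_key[mod_of_msg],
    author_id = paste0(session_key[mod_of_msg], "_MOD"),
    author_role = "moderator",
    t_min = stats::runif(sum(n_mod)) * duration[mod_of_msg],
    text = sprintf("moderator reply %d", sequence(n_mod[n_mod > 0L]))
  )
  transcripts <- rbind(msg_user, msg_mod)

  sessions <- tibble::tibble(
    session_key = sk, user_id = uid,
    struggle_text = paste0("I am struggling with ", topic, "."),
    topic = topic, device = device, duration_min = dur
  )
  corpus <- chat_corpus(sessions, transcripts)

  # scored units: the struggle at t = 0 plus every user message
  unit_row <- c(seq_len(nu), row_of_msg)
  unit_t <- c(rep(0, nu), t_msg)
  t_eff <- pmin(unit_t, dur[unit_row])
  L <- latent_loneliness(t_eff, l0[unit_row], cfg$l_end,
                         params$decay_rate[unit_row], cfg$t_lag)
  O <- latent_optimism(t_eff, o0[unit_row], cfg$o_end,
                       params$rise_rate[unit_row], cfg$rise_mid)
  lon_obs <- pmin(pmax(round(L + stats::rnorm(length(L), 0,
                                              cfg$sigma_obs)), 1), 10)
  opt_obs <- observe_optimism_raw(O, cfg$sigma_obs_optimism,
                                  stats::runif(length(O)))
  scores <- tibble::tibble(
    session_key = rep(sk[unit_row], 2L),
    user_id = rep(uid[unit_row], 2L),
    t_min = rep(unit_t, 2L),
    emotion = rep(c("loneliness", "optimism"), each = length(unit_t)),
    value = c(lon_obs, opt_obs)
  )
  scores_nf <- scores
  scores_nf$value <- c(pmin(pmax(round(L), 1), 10),
                       observe_optimism_raw(O, 0))

  grid <- 0:68
  t_grid <- pmin(matrix(grid, nu, length(grid), byrow = TRUE), dur)
  L_grid <- latent_loneliness(t_grid, l0, cfg$l_end, params$decay_rate,
                              cfg$t_lag)
  O_grid <- latent_optimism(t_grid, o0, cfg$o_end, params$rise_rate,
                            cfg$rise_mid)
  dimnames(L_grid) <- dimnames(O_grid) <-
    list(paste(sk, uid, sep = "\r"), as.character(grid))

  list(
    corpus = corpus,
    scores = scores,
    truth = list(
      params = params,
      latent_loneliness = L_grid,
      latent_optimism = O_grid,
      scores_noisefree = scores_nf,
      config = cfg,
      seed = seed
    )
  )
}

#' Oracle significance onset from noise-free latents
#'
#' Runs the standard trend pipeline (inclusion filter, gridding,
#' aggregation, onset detection) on the generator's *noise-free* score
#' table, yielding the onset the noisy pipeline is expected to recover.
#'
#' @param sim A [generate_corpus()] result.
#' @param emotion An [emotion_spec()] or emotion name.
#' @param reference_minute,alpha,grid_max As in [run_trend()].
#' @return The oracle onset minute (`NA` if none).
#' @export
oracle_onset <- function(sim, emotion, reference_minute = 5, alpha = 0.05,
                         grid_max = 68) {
  res <- run_trend(sim$corpus, sim$truth$scores_noisefree, emotion,
                   reference_minute = reference_minute, alpha = alpha,
                   grid_max = grid_max)
  res$summary$onset_minute
}

#' Oracle cohort divergence from noise-free latents
#'
#' Runs the full matched-cohort comparison (propensity fit, caliper
#' matching, per-emotion filter, between-cohort tests) on the generator's
#' noise-free score table.
#'
#' @inheritParams oracle_onset
#' @param seed Tie-break seed passed to the matcher.
#' @param caliper_fraction See [propensity_match()].
#' @return The oracle divergence minute (`NA` if none).
#' @export
oracle_divergence <- function(sim, emotion, reference_minute = 5,
                              alpha = 0.05, grid_max = 68, seed = 1L,
                              caliper_fraction = 0.25) {
  res <- run_compare(sim$corpus, sim$truth$scores_noisefree, emotion,
                     reference_minute = reference_minute, alpha = alpha,
                     grid_max = grid_max, seed = seed,
                     caliper_fraction = caliper_fraction)
  res$comparison$divergence_minute
}
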