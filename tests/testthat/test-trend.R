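test_that("the loneliness inclusion threshold is strict", {
  expect_true(include_session("loneliness", struggle_score = 6,
                              message_count = 3))
  expect_false(include_session("loneliness", struggle_score = 5,
                               message_count = 3))
  expect_true(include_session("optimism", struggle_score = -1,
                              message_count = 1))
  # sessions without messages are never analyzable
  expect_false(include_session("optimism", struggle_score = 1,
                               message_count = 0))
  expect_false(include_session("loneliness", struggle_score = 9,
                               message_count = 0))
})

test_that("gridding interpolates linearly and extrapolates constantly", {
  g <- grid_trajectory(list(t_min = c(2, 4), value = c(6, 8)))
  expect_length(g, 69L)
  expect_equal(unname(g[["3"]]), 7)
  expect_equal(unname(g[as.character(0:2)]), rep(6, 3))
  expect_equal(unname(g[as.character(4:68)]), rep(8, 65))

  g1 <- grid_trajectory(list(t_min = 0, value = 9))
  expect_equal(unname(g1), rep(9, 69))

  pts <- list(t_min = 0:68, value = stats::runif(69))
  expect_equal(unname(grid_trajectory(pts)), pts$value)

  expect_error(grid_trajectory(list(t_min = numeric(0), value = numeric(0))),
               class = "ptr_validation_error")
})

test_that("monotone series yield monotone grids", {
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:10, 1)
    t <- sort(stats::runif(k, 0, 70))
    v <- sort(stats::runif(k, 1, 10))
    g <- grid_trajectory(list(t_min = t, value = v))
    expect_true(all(diff(g) >= -1e-12))
  }
})

test_that("aggregation computes cross-user mean and population SD", {
  traj <- rbind(rep(4, 69), rep(6, 69))
  colnames(traj) <- as.character(0:68)
  trend <- aggregate_trend(traj, "loneliness")
  expect_equal(trend$mean, rep(5, 69))
  expect_equal(trend$sd, rep(1, 69)) # population SD of {4, 6}
  expect_equal(trend$n, rep(2L, 69))
  expect_true(is.na(trend$p_value[trend$minute == 5]))

  expect_error(aggregate_trend(traj[1, , drop = FALSE], "loneliness"),
               class = "ptr_validation_error")
})

test_that("aggregating series of mixed emotions is an error", {
  s1 <- structure(tibble::tibble(t_min = c(0, 2), value = c(5, 6)),
                  emotion = "loneliness")
  s2 <- structure(tibble::tibble(t_min = c(0, 2), value = c(0, 1)),
                  emotion = "optimism")
  expect_error(aggregate_trend(list(s1, s2), "loneliness"),
               "mix", class = "ptr_validation_error")
})

test_that("the aggregate mean tracks the latent mean within Monte Carlo error", {
  sim <- generate_corpus(generator_config(n_sessions = 220,
                                          group_fraction = 0), seed = 31)
  res <- suppressWarnings(run_trend(sim$corpus, sim$scores, "optimism"))
  # the optimism trend includes every session with messages, so the latent
  # rows can be aligned exactly
  s <- sim$corpus$sessions
  inc <- s$message_count >= 1
  keys <- paste(s$session_key[inc], s$user_id[inc], sep = "\r")
  latent <- sim$truth$latent_optimism[keys, , drop = FALSE]
  for (m in c("5", "20", "40", "68")) {
    se <- stats::sd(latent[, m]) / sqrt(nrow(latent))
    expect_lt(abs(res$trend$mean[res$trend$minute == as.numeric(m)] -
                    mean(latent[, m])),
              3 * se + 0.06) # + ordered-logit discretization allowance
  }
})

test_that("percent change is signed by improvement and matches arithmetic", {
  mk_trend <- function(means, emotion) {
    structure(
      tibble::tibble(minute = 0:68, mean = means, sd = 1, n = 10,
                     p_value = 0.01),
      emotion = emotion, reference_minute = 5,
      alternative = if (emotion == "loneliness") "less" else "greater",
      class = c("aggregate_trend", class(tibble::tibble()))
    )
  }
  # loneliness falling 10 -> 5 is a 50% improvement
  tr <- mk_trend(c(rep(10, 6), seq(10, 5, length.out = 63)), "loneliness")
  expect_equal(percent_change(tr, 68), 50)
  # no change at the reference itself
  expect_equal(percent_change(tr, 5), 0)
  # the published-style means: 6.47 at the reference, 4.29 at the end
  tr2 <- mk_trend(c(rep(6.47, 6), seq(6.47, 4.29, length.out = 63)),
                  "loneliness")
  expect_equal(percent_change(tr2, 68), 100 * (6.47 - 4.29) / 6.47,
               tolerance = 1e-12)
  expect_equal(percent_change(tr2, 68), 33.69, tolerance = 1e-3)
  # a loneliness increase is a negative percent change
  tr3 <- mk_trend(c(rep(4, 6), seq(4, 5, length.out = 63)), "loneliness")
  expect_lt(percent_change(tr3, 68), 0)
  # zero reference mean cannot be a denominator
  tr4 <- mk_trend(rep(0, 69), "optimism")
  expect_error(percent_change(tr4, 68), class = "ptr_validation_error")
})

test_that("onset is the start of the all-significant suffix", {
  mk <- function(p) {
    structure(
      tibble::tibble(minute = 0:68, mean = 5, sd = 1, n = 10, p_value = p),
      emotion = "loneliness", reference_minute = 5, alternative = "less",
      class = c("aggregate_trend", class(tibble::tibble()))
    )
  }
  p <- rep(0.01, 69)
  p[6] <- NA # reference
  p[1:5] <- NA
  expect_equal(detect_onset(mk(replace(p, 6, NA))), 6) # reference + 1
  p2 <- p
  p2[tt <- which(0:68 == 20)] <- 0.2 # one non-significant minute at 20
  expect_equal(detect_onset(mk(p2)), 21)
  p3 <- p
  p3[69] <- 0.3 # last minute fails: no onset at all
  expect_true(is.na(detect_onset(mk(p3))))
})

test_that("raising alpha never delays the onset", {
  set.seed(17)
  sim <- small_sim(seed = 17, n = 60, group_fraction = 0)
  trend <- suppressWarnings(
    run_trend(sim$corpus, sim$scores, "loneliness"))$trend
  onsets <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a) {
    o <- detect_onset(trend, alpha = a)
    if (is.na(o)) 69 else o
  }, numeric(1))
  expect_true(all(diff(onsets) <= 0))
})

test_that("the trend summary reports start, end, changes and onset", {
  sim <- small_sim(seed = 23, n = 80, group_fraction = 0)
  res <- suppressWarnings(run_trend(sim$corpus, sim$scores, "loneliness"))
  s <- res$summary
  expect_equal(s$start_value,
               res$trend$mean[res$trend$minute == 5])
  expect_equal(s$end_value, res$trend$mean[res$trend$minute == 68])
  expect_gt(s$pct_change_at_end, 0) # loneliness falls under the defaults
  expect_equal(s$n, res$trend$n[1])
})
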