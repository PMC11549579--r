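test_that("cohorts split on distinct messaging users per room", {
  corpus <- worked_example_corpus() # 2 users + moderator
  s <- split_cohorts(corpus)
  expect_equal(unique(s$cohort), "group")

  single <- chat_corpus(
    tibble::tibble(session_key = "R1", user_id = "A", struggle_text = "s",
                   topic = "stress", device = "desktop"),
    tibble::tibble(session_key = "R1",
                   author_id = c("A", "M"),
                   author_role = c("user", "moderator"),
                   t_min = c(1, 2), text = c("x", "y"))
  )
  expect_equal(split_cohorts(single)$cohort, "single")

  big <- chat_corpus(
    tibble::tibble(session_key = "R1", user_id = c("A", "B", "C", "D"),
                   struggle_text = "s", topic = "stress",
                   device = "desktop"),
    tibble::tibble(session_key = "R1",
                   author_id = c("A", "B", "C", "D", "M"),
                   author_role = c(rep("user", 4), "moderator"),
                   t_min = 1:5, text = paste0("t", 1:5))
  )
  expect_equal(split_cohorts(big)$cohort, rep("group", 4))

  silent <- chat_corpus(
    tibble::tibble(session_key = "R1", user_id = "A", struggle_text = "s",
                   topic = "stress", device = "desktop"),
    tibble::tibble(session_key = "R1", author_id = "M",
                   author_role = "moderator", t_min = 1, text = "hi")
  )
  expect_warning(out <- split_cohorts(silent), "no user messages")
  expect_equal(nrow(out), 0L)
})

test_that("the caliper is a quarter of the pooled population SD", {
  expect_equal(compute_caliper(c(0.3, 0.7)), 0.25 * 0.2) # pop SD is 0.2
  expect_equal(compute_caliper(rep(0.4, 5)), 0)
  expect_error(compute_caliper(0.5), class = "ptr_validation_error")
  # pooled over both cohorts, not either one alone
  single_p <- c(0.1, 0.1, 0.1)
  group_p <- c(0.9, 0.9)
  pooled <- c(single_p, group_p)
  expect_equal(compute_caliper(pooled),
               0.25 * sqrt(mean((pooled - mean(pooled))^2)))
  expect_gt(compute_caliper(pooled), compute_caliper(single_p + 1e-9 * seq(3)))
})

test_that("nearest-neighbor matching respects the caliper", {
  single <- tibble::tibble(session_key = "s1", user_id = "u1",
                           propensity = 0.50)
  group <- tibble::tibble(session_key = c("g1", "g2"),
                          user_id = c("u1", "u2"),
                          propensity = c(0.52, 0.70))
  res <- match_cohorts(single, group, caliper = 0.05)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$group_session_key, "g1")
  expect_equal(res$unmatched_group$session_key, "g2")

  far <- tibble::tibble(session_key = "g1", user_id = "u1",
                        propensity = 0.60)
  res2 <- match_cohorts(single, far, caliper = 0.05)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$unmatched_single$session_key, "s1")

  expect_error(match_cohorts(single[0, ], group, 0.1),
               class = "ptr_validation_error")
})

test_that("matching contracts hold on random cohorts and are seed-stable", {
  set.seed(101)
  for (i in 1:20) {
    ns <- sample(10:40, 1)
    ng <- sample(10:40, 1)
    single <- tibble::tibble(session_key = paste0("s", 1:ns),
                             user_id = "u", propensity = stats::runif(ns))
    group <- tibble::tibble(session_key = paste0("g", 1:ng),
                            user_id = "u", propensity = stats::runif(ng))
    cal <- compute_caliper(c(single$propensity, group$propensity))
    res <- match_cohorts(single, group, cal, seed = i)
    expect_true(all(res$pairs$delta <= cal + 1e-12))
    expect_false(any(duplicated(res$pairs$group_session_key)))
    res_again <- match_cohorts(single, group, cal, seed = i)
    expect_identical(res$pairs, res_again$pairs)
  }
})

test_that("matching improves the initial-intensity balance", {
  set.seed(202)
  improved <- 0
  for (i in 1:20) {
    n <- 120
    y <- rbinom(n, 1, 0.5)
    intensity <- stats::rnorm(n, 5 + 1.2 * y, 1.5)
    feats <- session_features(sample(chat_topics, n, replace = TRUE),
                              sample(chat_devices, n, replace = TRUE),
                              intensity)
    fit <- suppressWarnings(fit_propensity(feats, y))
    p <- predict_propensity(fit, feats)
    cal <- compute_caliper(p)
    single <- tibble::tibble(session_key = paste0("x", which(y == 0)),
                             user_id = "u", propensity = p[y == 0])
    group <- tibble::tibble(session_key = paste0("x", which(y == 1)),
                            user_id = "u", propensity = p[y == 1])
    res <- match_cohorts(single, group, cal, seed = i)
    matched_ids <- as.integer(sub("x", "", c(res$pairs$single_session_key,
                                             res$pairs$group_session_key)))
    bal <- balance_table(feats, y, matched_ids)
    smd <- bal[bal$feature == "intensity", ]
    improved <- improved + (abs(smd$smd_after) <= abs(smd$smd_before))
  }
  expect_gte(improved / 20, 0.95)
})

test_that("comparing a cohort against itself finds no divergence", {
  sim <- small_sim(seed = 33, n = 60, group_fraction = 0.5)
  m <- suppressWarnings(propensity_match(sim$corpus, sim$scores, "optimism"))
  # force a self-comparison: both sides of each pair are the same session
  m$pairs$group_session_key <- m$pairs$single_session_key
  m$pairs$group_user_id <- m$pairs$single_user_id
  cmp <- compare_cohorts(m, sim$scores, "optimism")
  expect_true(is.na(cmp$divergence_minute))
  expect_true(all(abs(cmp$between_p$p_value - 0.5) < 0.5))
  expect_equal(cmp$trend_single$mean, cmp$trend_group$mean)
})

test_that("emptying a cohort through the emotion filter is an error", {
  sim <- small_sim(seed = 44, n = 40, group_fraction = 0.5,
                   l0_mean = 2, l0_min = 1, l0_max = 4, sigma_obs = 0)
  m <- suppressWarnings(propensity_match(sim$corpus, sim$scores,
                                         "loneliness"))
  expect_error(compare_cohorts(m, sim$scores, "loneliness"),
               class = "ptr_validation_error")
})
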