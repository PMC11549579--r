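test_that("scoring contexts reproduce the worked five-message example", {
  corpus <- worked_example_corpus()

  ua <- build_units(user_session(corpus, "S1", "A"))
  expect_equal(ua$target_text, c("struggle of A", "m1", "m4"))
  expect_equal(ua$context_text, c("", "", "m2\nm3"))
  expect_equal(ua$t_min, c(0, 1, 4))

  ub <- build_units(user_session(corpus, "S1", "B"))
  expect_equal(ub$target_text, c("struggle of B", "m2", "m5"))
  expect_equal(ub$context_text, c("", "", "m3\nm4"))
})

test_that("a user with only a struggle yields one unit with empty context", {
  sessions <- tibble::tibble(session_key = "S1", user_id = "A",
                             struggle_text = "s", topic = "stress",
                             device = "desktop")
  transcripts <- tibble::tibble(session_key = "S1", author_id = "M",
                                author_role = "moderator", t_min = 1,
                                text = "hi")
  corpus <- chat_corpus(sessions, transcripts)
  units <- build_units(user_session(corpus, "S1", "A"))
  expect_equal(nrow(units), 1L)
  expect_true(units$is_struggle)
  expect_equal(units$context_text, "")
})

test_that("contexts are causal and partition the other-author messages", {
  for (seed in 1:5) {
    sim <- small_sim(seed = seed, n = 8, group_fraction = 1)
    s <- sim$corpus$sessions
    tr <- sim$corpus$transcripts
    for (i in which(s$message_count > 0)) {
      units <- build_units(user_session(sim$corpus, s$session_key[i],
                                        s$user_id[i]))
      ctx_texts <- unlist(strsplit(units$context_text[
        nzchar(units$context_text)], "\n", fixed = TRUE))
      # each other-author message appears in at most one context
      expect_false(any(duplicated(ctx_texts)))
      room <- tr[tr$session_key == s$session_key[i], ]
      for (k in seq_len(nrow(units))) {
        if (!nzchar(units$context_text[k])) next
        parts <- strsplit(units$context_text[k], "\n", fixed = TRUE)[[1]]
        t_ctx <- room$t_min[match(parts, room$text)]
        expect_true(all(t_ctx <= units$t_min[k] + 1e-12))
        expect_true(all(room$author_id[match(parts, room$text)] !=
                          s$user_id[i]))
      }
    }
  }
})

test_that("replaying a score table through the pipeline reproduces it", {
  sim <- small_sim(seed = 7, n = 10)
  scorer <- scorer_replay(sim$scores)
  s <- sim$corpus$sessions
  for (i in seq_len(nrow(s))) {
    for (em in c("loneliness", "optimism")) {
      series <- score_session(user_session(sim$corpus, s$session_key[i],
                                           s$user_id[i]), scorer, em)
      rows <- sim$scores[sim$scores$session_key == s$session_key[i] &
                           sim$scores$user_id == s$user_id[i] &
                           sim$scores$emotion == em, ]
      ord <- order(rows$t_min)
      expect_identical(series$t_min, rows$t_min[ord])
      expect_identical(series$value, rows$value[ord])
    }
  }
})

test_that("same-time scores are averaged into one point", {
  sessions <- tibble::tibble(session_key = "S1", user_id = "A",
                             struggle_text = "s", topic = "stress",
                             device = "desktop")
  transcripts <- tibble::tibble(
    session_key = "S1", author_id = "A", author_role = "user",
    t_min = c(3, 3), text = c("x1", "x2")
  )
  corpus <- chat_corpus(sessions, transcripts)
  vals <- c(8, 4, 6) # struggle, then the two messages
  k <- 0
  scorer <- function(unit, emotion) {
    k <<- k + 1
    vals[k]
  }
  series <- score_session(user_session(corpus, "S1", "A"), scorer,
                          "loneliness")
  expect_equal(series$t_min, c(0, 3))
  expect_equal(series$value, c(8, 5))
})

test_that("out-of-range scorer values raise an error naming the unit", {
  corpus <- worked_example_corpus()
  scorer <- function(unit, emotion) 42
  expect_error(
    score_session(user_session(corpus, "S1", "A"), scorer, "loneliness"),
    "outside the loneliness raw scale", class = "ptr_scorer_error"
  )
})

test_that("the noiseless synthetic scorer returns discretized latents", {
  sim <- small_sim(seed = 9, n = 8, sigma_obs = 0, sigma_obs_optimism = 0)
  scorer <- scorer_synthetic(sim$truth, sigma_obs = 0)
  s <- sim$corpus$sessions
  i <- which(s$message_count > 0)[1]
  ses <- user_session(sim$corpus, s$session_key[i], s$user_id[i])
  series <- score_session(ses, scorer, "loneliness")
  p <- sim$truth$params
  j <- which(p$session_key == s$session_key[i] & p$user_id == s$user_id[i])
  expected <- pmin(pmax(round(latent_loneliness(
    pmin(series$t_min, p$duration_min[j]),
    p$l0[j], p$l_end[j], p$decay_rate[j], p$t_lag[j])), 1), 10)
  expect_equal(series$value, expected)
})

test_that("prompts carry the anchors verbatim and are byte-stable", {
  corpus <- worked_example_corpus()
  unit <- build_units(user_session(corpus, "S1", "A"))[3, ]
  p_lon <- assemble_prompt("loneliness", unit)
  expect_match(p_lon, "I just always feel totally alone.", fixed = TRUE)
  expect_match(p_lon, "10=high", fixed = TRUE)
  p_opt <- assemble_prompt("optimism", unit)
  expect_match(p_opt, "I am optimistic that I might slowly get better.",
               fixed = TRUE)
  expect_match(p_opt, "1=positive", fixed = TRUE)
  expect_identical(p_lon, assemble_prompt("loneliness", unit))
  expect_error(assemble_prompt("loneliness", unit,
                               anchors = fewshot_anchors("/nonexistent")),
               class = "ptr_config_error")
})
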