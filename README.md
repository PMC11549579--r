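# peertrends

Momentary loneliness and optimism trends in moderated peer-support chats.

Digital peer-support services pair a user who submits a short free-text
"struggle" with peers and a trained moderator in a live chat. peertrends is
an R package for quantifying, from the timestamped transcripts of such
sessions, how momentary loneliness (scored 1-10 per message) and optimism
(scored -1/0/+1, reported on [0, 1]) evolve minute by minute - and whether
chatting alongside peers (moderator + small group) improves those
trajectories compared with one-on-one sessions (moderator + single user).

The pipeline, end to end:

1. **Scoring contexts** (`build_units()`, `score_session()`): each user
   message is scored together with the other-author messages exchanged
   since that user's previous message; the struggle and the first message
   are scored with an empty context. Scores come from a pluggable scorer
   (replay table, synthetic generator, or an external text-model adapter
   whose prompts `assemble_prompt()` builds from packaged few-shot
   anchors).
2. **Trajectories and trends** (`grid_trajectory()`, `aggregate_trend()`):
   per-user series are gridded on minutes 0-68 (linear interpolation,
   constant extrapolation) and aggregated across users into mean / SD / n
   per minute. Loneliness sessions qualify only when the struggle scores
   strictly above 5; every session with messages qualifies for optimism.
3. **Significance onset** (`mann_whitney_one_sided()`, `detect_onset()`):
   each minute is compared with the 5-minute reference by a one-sided
   Mann-Whitney U test (exact permutation enumeration for small samples,
   tie- and continuity-corrected normal approximation otherwise); the
   onset is the first minute from which p < .05 holds through minute 68.
4. **Matched cohorts** (`propensity_match()`, `compare_cohorts()`):
   sessions are split into single-user vs small-group cohorts, aligned by
   a ridge-stabilized logistic propensity model on topic, device and
   initial emotional intensity, matched 1:1 by nearest neighbor within a
   caliper of 25% of the pooled propensity SD, and compared minute by
   minute to find when the group cohort consistently outperforms.
5. **Synthetic corpora** (`generate_corpus()`): a seeded generator with
   exported latent ground truth (durations, silent users, topic/device
   mixes, decaying loneliness, rising optimism, configurable peer effect)
   so the whole pipeline is testable without any real data.

Transcripts travel as JSONL (session headers + messages), scores as CSV
replay tables, trends as CSV, summaries and match reports as JSON; see
`?read_sessions`, `?read_score_table`, `?write_trend`.

## Worked example

```r
library(peertrends)

sim <- generate_corpus(
  generator_config(n_sessions = 400, group_rate_multiplier = 1.5),
  seed = 42
)

res <- run_trend(sim$corpus, sim$scores, "loneliness", quiet = FALSE)
#> [loneliness] funnel: 715 sessions -> 514 with messages -> 422 included
s <- res$summary
sprintf("n = %d | 5 min: %.2f (SD %.2f) -> 68 min: %.2f (SD %.2f)",
        s$n, s$start_value, s$sd_start, s$end_value, s$sd_end)
#> "n = 422 | 5 min: 5.58 (SD 1.14) -> 68 min: 4.06 (SD 1.78)"
sprintf("change at 68 min: %.1f%% | at 19.4 min: %.1f%% | onset: minute %d",
        s$pct_change_at_end, s$pct_change_at, s$onset_minute)
#> "change at 68 min: 27.1% | at 19.4 min: 22.1% | onset: minute 6"

cmp <- run_compare(sim$corpus, sim$scores, "loneliness", quiet = FALSE)
#> [loneliness] cohorts: 135 single / 379 group -> 133 pairs -> 110 / 113 after filter
cmp$comparison$divergence_minute
#> [1] 1
```

Reading the output: 715 user chat sessions were simulated in 400 rooms;
514 users sent at least one message, and 422 of those opened with a
struggle scoring above 5 on loneliness, so they form the loneliness trend.
Mean momentary loneliness falls from 5.58 at the 5-minute reference to
4.06 at minute 68, a 27.1% drop, significant from minute 6 onward. After
propensity matching (133 pairs; the unequal 110 / 113 is the loneliness
filter applied inside each matched cohort), the small-group cohort's
decline consistently outpaces the single-user cohort's from minute 1,
consistent with the simulated peer effect (a 1.5x faster latent decay in
group rooms).

A command-line wrapper over the same functions is installed as
`exec/peertrends` (`peertrends simulate|trend|compare`); every run writes
its artifacts plus a manifest (resolved config, seed, input digests).

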