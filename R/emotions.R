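#' Topic vocabulary for session struggles
#'
#' The fixed 14-topic vocabulary used to label the struggle of a user chat
#' session. Topics are inputs to the pipeline (assigned upstream), and enter
#' the analysis only as propensity-matching covariates.
#'
#' @format Character vector of length 14.
#' @export
chat_topics <- c(
  "physical health or medical",
  "social connection",
  "loneliness",
  "anxiety",
  "mental health conditions excluding anxiety and depression",
  "trauma",
  "depression",
  "caregiving or parenting",
  "stress",
  "identity",
  "finances",
  "productivity or work",
  "suicide or self-harm",
  "other"
)

#' Device vocabulary
#'
#' @format Character vector of length 3.
#' @export
chat_devices <- c("desktop", "mobile", "tablet")

#' Emotion specification
#'
#' Describes how one of the two tracked emotions is scored and reported.
#' Momentary loneliness is scored as an intensity on 1-10 (1 = low,
#' 5 = moderate, 10 = high); a session enters the loneliness trend only when
#' its struggle scores strictly above 5. Optimism is scored as a valence in
#' \{-1, 0, +1\} (negative / neutral / positive) and mapped to the reporting
#' scale [0, 1] by \code{v -> (v + 1) / 2}, so reported values below 0.3 are
#' "negative" and above 0.7 "positive"; every session with at least one
#' message enters the optimism trend.
#'
#' @param name `"loneliness"` or `"optimism"`.
#'
#' @return An object of class `emotion_spec`: a list with fields `name`,
#'   `scale_kind`, `raw_range`, `raw_values` (discrete raw levels or `NULL`),
#'   `inclusion_threshold` (`NA` when every session is included),
#'   `improvement_direction` (`"decrease"` or `"increase"`),
#'   `zones` (tibble with `label`, `lo`, `hi` on the reporting scale), and
#'   `to_reporting` (function mapping raw to reporting values).
#' @examples
#' spec <- emotion_spec("optimism")
#' spec$to_reporting(c(-1, 0, 1))
#' @export
emotion_spec <- function(name = c("loneliness", "optimism")) {
  name <- match.arg(name)
  if (name == "loneliness") {
    out <- list(
      name = "loneliness",
      scale_kind = "intensity_1_10",
      raw_range = c(1, 10),
      raw_values = NULL,
      inclusion_threshold = 5,
      improvement_direction = "decrease",
      zones = tibble::tibble(
        label = c("low", "moderate", "high"),
        lo = c(1, 4, 7),
        hi = c(4, 7, 10)
      ),
      to_reporting = identity,
      reporting_range = c(1, 10)
    )
  } else {
    out <- list(
      name = "optimism",
      scale_kind = "valence_neg_neu_pos",
      raw_range = c(-1, 1),
      raw_values = c(-1, 0, 1),
      inclusion_threshold = NA_real_,
      improvement_direction = "increase",
      zones = tibble::tibble(
        label = c("negative", "neutral", "positive"),
        lo = c(0, 0.3, 0.7),
        hi = c(0.3, 0.7, 1)
      ),
      to_reporting = function(v) (v + 1) / 2,
      reporting_range = c(0, 1)
    )
  }
  structure(out, class = "emotion_spec")
}

#' @export
print.emotion_spec <- function(x, ...) {
  cat(sprintf(
    "<emotion_spec> %s (%s), improvement = %s, inclusion threshold = %s\n",
    x$name, x$scale_kind, x$improvement_direction,
    if (is.na(x$inclusion_threshold)) "none" else
      paste0("> ", format(x$inclusion_threshold))
  ))
  invisible(x)
}

#' Zone label for a reported emotion value
#'
#' Maps a value on the reporting scale to its qualitative zone (loneliness:
#' low (1,4], moderate (4,7], high (7,10]; optimism: negative < 0.3, neutral
#' 0.3-0.7, positive > 0.7).
#'
#' @param spec An [emotion_spec()].
#' @param value Numeric vector on the reporting scale.
#' @return Character vector of zone labels.
#' @export
emotion_zone <- function(spec, value) {
  stopifnot(inherits(spec, "emotion_spec"))
  z <- spec$zones
  out <- rep(NA_character_, length(value))
  # lowest zone is closed at its lower bound, others half-open (lo, hi]
  for (i in seq_len(nrow(z))) {
    sel <- if (i == 1L) {
      value >= z$lo[i] & value <= z$hi[i]
    } else {
      value > z$lo[i] & value <= z$hi[i]
    }
    out[sel] <- z$label[i]
  }
  out
}
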