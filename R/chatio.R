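#' @keywords internal
ptr_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "peertrends_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct a chat corpus
#'
#' A `chat_corpus` bundles room-level transcripts with user-level session
#' headers. Each row of `sessions` is one *user chat session*: one user's
#' participation in one room, opened by that user's free-text struggle
#' (at most 300 characters), labeled with a topic from [chat_topics] and a
#' device from [chat_devices]. `transcripts` holds one row per message:
#' `session_key`, `author_id`, `author_role` (`"user"` or `"moderator"`),
#' `t_min` (fractional minutes since session start; the struggle defines
#' t = 0), and non-empty `text`.
#'
#' @param sessions Data frame with columns `session_key`, `user_id`,
#'   `struggle_text`, `topic`, `device`, and optionally `duration_min`.
#' @param transcripts Data frame with columns `session_key`, `author_id`,
#'   `author_role`, `t_min`, `text`. May have zero rows.
#'
#' @return An object of class `chat_corpus`: a list with tibbles `sessions`
#'   (ordered by `(session_key, user_id)`, with derived `message_count` and
#'   `duration_min`) and `transcripts` (ordered by `(session_key, t_min)`).
#' @export
chat_corpus <- function(sessions, transcripts) {
  sessions <- tibble::as_tibble(sessions)
  transcripts <- tibble::as_tibble(transcripts)
  need_s <- c("session_key", "user_id", "struggle_text", "topic", "device")
  need_t <- c("session_key", "author_id", "author_role", "t_min", "text")
  miss <- setdiff(need_s, names(sessions))
  if (length(miss)) {
    ptr_error(paste0("sessions is missing column(s): ",
                     paste(miss, collapse = ", ")), "ptr_validation_error")
  }
  miss <- setdiff(need_t, names(transcripts))
  if (length(miss)) {
    ptr_error(paste0("transcripts is missing column(s): ",
                     paste(miss, collapse = ", ")), "ptr_validation_error")
  }

  key <- paste(sessions$session_key, sessions$user_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ptr_error(paste0("duplicate session header for (session_key, user_id): ",
                     gsub("\r", ", ", dup, fixed = TRUE)),
              "ptr_validation_error")
  }
  bad <- which(!sessions$topic %in% chat_topics)
  if (length(bad)) {
    ptr_error(paste0("unknown topic '", sessions$topic[bad[1]],
                     "' for user ", sessions$user_id[bad[1]]),
              "ptr_validation_error")
  }
  bad <- which(!sessions$device %in% chat_devices)
  if (length(bad)) {
    ptr_error(paste0("unknown device '", sessions$device[bad[1]],
                     "' for user ", sessions$user_id[bad[1]]),
              "ptr_validation_error")
  }
  bad <- which(is.na(sessions$struggle_text) |
                 !nzchar(sessions$struggle_text) |
                 nchar(sessions$struggle_text) > 300L)
  if (length(bad)) {
    ptr_error(paste0("struggle_text must be non-empty and at most 300 ",
                     "characters (user ", sessions$user_id[bad[1]], ")"),
              "ptr_validation_error")
  }
  if (nrow(transcripts)) {
    if (any(is.na(transcripts$t_min) | transcripts$t_min < 0)) {
      ptr_error("transcript t_min must be >= 0", "ptr_validation_error")
    }
    if (any(!transcripts$author_role %in% c("user", "moderator"))) {
      ptr_error("author_role must be 'user' or 'moderator'",
                "ptr_validation_error")
    }
    if (any(is.na(transcripts$text) | !nzchar(transcripts$text))) {
      ptr_error("message text must be non-empty", "ptr_validation_error")
    }
    orphan <- setdiff(
      transcripts$session_key[transcripts$author_role == "user"],
      sessions$session_key
    )
    # user-authored messages in a room with no session header at all
    if (length(orphan)) {
      ptr_error(paste0("transcript references unknown session_key: ",
                       orphan[1]), "ptr_validation_error")
    }
    ord <- order(transcripts$session_key, transcripts$t_min)
    transcripts <- transcripts[ord, , drop = FALSE]
  }

  ord <- order(sessions$session_key, sessions$user_id)
  sessions <- sessions[ord, , drop = FALSE]

  ukey <- paste(transcripts$session_key, transcripts$author_id, sep = "\r")
  skey <- paste(sessions$session_key, sessions$user_id, sep = "\r")
  cnt <- table(ukey)
  sessions$message_count <- as.integer(cnt[skey])
  sessions$message_count[is.na(sessions$message_count)] <- 0L

  if (!"duration_min" %in% names(sessions) ||
      all(is.na(sessions$duration_min))) {
    dmax <- tapply(transcripts$t_min, transcripts$session_key, max)
    sessions$duration_min <- unname(dmax[sessions$session_key])
    sessions$duration_min[is.na(sessions$duration_min)] <- 0
  }

  structure(list(sessions = sessions, transcripts = transcripts),
            class = "chat_corpus")
}

#' @export
print.chat_corpus <- function(x, ...) {
  cat(sprintf(
    "<chat_corpus> %d user chat sessions in %d rooms, %d messages\n",
    nrow(x$sessions), length(unique(x$sessions$session_key)),
    nrow(x$transcripts)
  ))
  invisible(x)
}

#' Read a chat corpus from JSONL
#'
#' The transcript file is one JSON object per line, with two record kinds:
#' `{"record":"session", "session_key":..., "user_id":..., "struggle_text":...,
#' "topic":..., "device":..., "duration_min":...}` (one per user chat session;
#' `duration_min` optional) and `{"record":"message", "session_key":...,
#' "author_id":..., "author_role":"user"|"moderator", "t_min":..., "text":...}`.
#' Files are UTF-8. Malformed lines raise a parse error naming the line
#' number; invalid topics, devices, or negative times raise validation
#' errors. An empty file yields an empty corpus.
#'
#' @param path Path to a JSONL transcript file.
#' @return A [chat_corpus()].
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) {
    ptr_error(paste0("no such file: ", path), "ptr_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ses <- list()
  msg <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        ptr_error(sprintf("line %d: malformed JSON (%s)", i,
                          conditionMessage(e)), "ptr_parse_error")
      }
    )
    kind <- rec$record
    if (is.null(kind) || !kind %in% c("session", "message")) {
      ptr_error(sprintf("line %d: unknown record kind", i), "ptr_parse_error")
    }
    if (kind == "session") {
      ses[[length(ses) + 1L]] <- rec
    } else {
      msg[[length(msg) + 1L]] <- rec
    }
  }
  grab <- function(recs, field, default = NA) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v) || length(v) != 1L || is.na(v)) return(default)
      if (is.character(default)) as.character(v) else as.numeric(v)
    }, FUN.VALUE = default)
  }
  sessions <- tibble::tibble(
    session_key = grab(ses, "session_key", NA_character_),
    user_id = grab(ses, "user_id", NA_character_),
    struggle_text = grab(ses, "struggle_text", NA_character_),
    topic = grab(ses, "topic", NA_character_),
    device = grab(ses, "device", NA_character_),
    duration_min = grab(ses, "duration_min", NA_real_)
  )
  transcripts <- tibble::tibble(
    session_key = grab(msg, "session_key", NA_character_),
    author_id = grab(msg, "author_id", NA_character_),
    author_role = grab(msg, "author_role", NA_character_),
    t_min = grab(msg, "t_min", NA_real_),
    text = grab(msg, "text", NA_character_)
  )
  chat_corpus(sessions, transcripts)
}

#' Write a chat corpus to JSONL
#'
#' Inverse of [read_sessions()]: session headers first (ordered by
#' `session_key`, `user_id`), then messages (ordered by `session_key`,
#' `t_min`). `read_sessions(write_sessions(corpus))` reproduces the corpus.
#'
#' @param corpus A [chat_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(corpus, path) {
  stopifnot(inherits(corpus, "chat_corpus"))
  s <- corpus$sessions
  tr <- corpus$transcripts
  ses_lines <- vapply(seq_len(nrow(s)), function(i) {
    jsonlite::toJSON(list(
      record = "session",
      session_key = s$session_key[i], user_id = s$user_id[i],
      struggle_text = s$struggle_text[i], topic = s$topic[i],
      device = s$device[i], duration_min = s$duration_min[i]
    ), auto_unbox = TRUE, digits = NA)
  }, FUN.VALUE = character(1))
  msg_lines <- vapply(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(list(
      record = "message",
      session_key = tr$session_key[i], author_id = tr$author_id[i],
      author_role = tr$author_role[i], t_min = tr$t_min[i],
      text = tr$text[i]
    ), auto_unbox = TRUE, digits = NA)
  }, FUN.VALUE = character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(ses_lines, msg_lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read / write a score replay table
#'
#' A replay table stores per-message emotion scores on each emotion's raw
#' scale, one row per scored unit: `session_key`, `user_id`, `t_min`
#' (the struggle is the row at t = 0), `emotion` (`"loneliness"` or
#' `"optimism"`), `value`. CSV, UTF-8.
#'
#' @param path CSV file path.
#' @return A tibble with the five columns above.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) {
    ptr_error(paste0("no such file: ", path), "ptr_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("session_key", "user_id", "t_min", "emotion", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ptr_error(paste0("score table missing column(s): ",
                     paste(miss, collapse = ", ")), "ptr_parse_error")
  }
  if (any(!df$emotion %in% c("loneliness", "optimism"))) {
    ptr_error("score table has unknown emotion", "ptr_validation_error")
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_score_table
#' @param scores Tibble of scores as described above.
#' @export
write_score_table <- function(scores, path) {
  need <- c("session_key", "user_id", "t_min", "emotion", "value")
  stopifnot(all(need %in% names(scores)))
  df <- as.data.frame(scores[need])
  df$t_min <- sprintf("%.12g", df$t_min)
  df$value <- sprintf("%.12g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an aggregate trend to CSV
#'
#' One row per grid minute with columns `minute`, `mean`, `sd`, `n`,
#' `p_value` (`NA` at the reference minute). Numbers are written with 12
#' significant digits so [read_trend()] round-trips the trend losslessly at
#' that precision.
#'
#' @param trend An aggregate trend tibble (see [aggregate_trend()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend <- function(trend, path) {
  need <- c("minute", "mean", "sd", "n", "p_value")
  miss <- setdiff(need, names(trend))
  if (length(miss)) {
    ptr_error(paste0("trend is missing column(s): ",
                     paste(miss, collapse = ", ")), "ptr_validation_error")
  }
  df <- as.data.frame(trend[need])
  for (col in c("minute", "mean", "sd", "p_value")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.12g", df[[col]]))
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) ptr_error(
                    paste0("cannot open for writing: ", path), "ptr_io_error"))
  on.exit(close(con))
  writeLines(paste(need, collapse = ","), con, useBytes = TRUE)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = ",")), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_trend
#' @export
read_trend <- function(path) {
  if (!file.exists(path)) {
    ptr_error(paste0("no such file: ", path), "ptr_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "NA", encoding = "UTF-8")
  tibble::as_tibble(df)
}

#' Extract one user chat session
#'
#' Returns the per-user view the scoring module operates on: the user's
#' struggle plus the full room transcript the user took part in.
#'
#' @param corpus A [chat_corpus()].
#' @param session_key,user_id Identify the user chat session.
#' @return A list of class `user_chat_session` with fields `session_key`,
#'   `user_id`, `struggle_text`, `topic`, `device`, `duration_min`,
#'   `message_count`, and `transcript` (tibble of the room's messages in
#'   time order).
#' @export
user_session <- function(corpus, session_key, user_id) {
  stopifnot(inherits(corpus, "chat_corpus"))
  i <- which(corpus$sessions$session_key == session_key &
               corpus$sessions$user_id == user_id)
  if (length(i) != 1L) {
    ptr_error(paste0("no session header for (", session_key, ", ",
                     user_id, ")"), "ptr_validation_error")
  }
  s <- corpus$sessions[i, ]
  tr <- corpus$transcripts[corpus$transcripts$session_key == session_key, ,
                           drop = FALSE]
  structure(list(
    session_key = session_key,
    user_id = user_id,
    struggle_text = s$struggle_text,
    topic = s$topic,
    device = s$device,
    duration_min = s$duration_min,
    message_count = s$message_count,
    transcript = tr
  ), class = "user_chat_session")
}
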