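#' @title Session logs: event taxonomy, parsing, and replay evaluation
#' @description Participant sessions are ordered streams of atomic
#'   diagnostic actions per case. The kinds modelled are
#'   `ADD_FINDING`, `ADD_HYPOTHESIS`, `ADD_DIAGNOSIS`, `ADD_LINK`,
#'   `DELETE_ITEM`, `MARK_CONFIDENCE`, and `CLOSE_CASE`. Confidence marks
#'   are entered after the case is concluded, so `MARK_CONFIDENCE` events
#'   must follow `CLOSE_CASE`.
#' @name session_log
NULL

EVENT_KINDS <- c("ADD_FINDING", "ADD_HYPOTHESIS", "ADD_DIAGNOSIS",
                 "ADD_LINK", "DELETE_ITEM", "MARK_CONFIDENCE", "CLOSE_CASE")

# Events that count as diagnostic actions for the sequence rules;
# DELETE_ITEM and MARK_CONFIDENCE are transparent to them.
ADD_KINDS <- c("ADD_FINDING", "ADD_HYPOTHESIS", "ADD_DIAGNOSIS", "ADD_LINK")

empty_events <- function() {
  data.frame(seq = integer(), kind = character(), label = character(),
             label2 = character(), polarity = character(), mark = character(),
             item_kind = character(), t = character(),
             stringsAsFactors = FALSE)
}

new_event <- function(seq, kind, label = NA_character_,
                      label2 = NA_character_, polarity = NA_character_,
                      mark = NA_character_, item_kind = NA_character_,
                      t = NA_character_) {
  data.frame(seq = as.integer(seq), kind = kind, label = label,
             label2 = label2, polarity = polarity, mark = mark,
             item_kind = item_kind, t = t, stringsAsFactors = FALSE)
}

new_case_record <- function(case_id, events) {
  events <- events[order(events$seq), , drop = FALSE]
  rownames(events) <- NULL
  list(case_id = case_id, events = events,
       completed = any(events$kind == "CLOSE_CASE"))
}

new_session <- function(participant, level, records) {
  structure(list(participant = participant, level = as.integer(level),
                 cases = records),
            class = "dxbias_session")
}

#' Parse a line-delimited session log
#'
#' Accepts JSONL (one event object per line with keys `participant`,
#' `level`, `case`, `seq`, `kind`, `payload`, optional `t`) or a CSV dialect
#' with columns `participant`, `level`, `case`, `seq`, `kind`, `label`,
#' `label2`, `polarity`, `mark`, `item_kind`, `t`. Payload conventions for
#' JSONL: a bare string for `ADD_FINDING`/`ADD_HYPOTHESIS`/`ADD_DIAGNOSIS`;
#' `{"finding":, "hypothesis":, "polarity":}` for `ADD_LINK`;
#' `{"item":, "mark": "sure"|"unsure", "item_kind":}` for `MARK_CONFIDENCE`;
#' `{"item":, "item_kind":}` for `DELETE_ITEM`; `null` for `CLOSE_CASE`.
#'
#' @param path path to the log file, or a character vector of JSONL lines.
#' @param format `"jsonl"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A `dxbias_sessions` object: a list of sessions, each holding the
#'   participant id, training level, and ordered per-case event streams.
#' @export
parse_session_log <- function(path, format = NULL) {
  if (length(path) == 1 && file.exists(path)) {
    if (is.null(format)) {
      format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "jsonl"
    }
    if (format == "csv") {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
      df$seq <- as.integer(df$seq)
      df$level <- as.integer(df$level)
      return(sessions_from_events(df))
    }
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- as.character(path)
  }
  lines_keep <- which(nzchar(trimws(lines)))
  rows <- vector("list", length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec)) {
      stop("session log line ", ln, ": malformed JSON", call. = FALSE)
    }
    for (k in c("participant", "case", "seq", "kind")) {
      if (is.null(rec[[k]])) {
        stop("session log line ", ln, ": missing field '", k, "'",
             call. = FALSE)
      }
    }
    if (!rec$kind %in% EVENT_KINDS) {
      stop("session log line ", ln, ": unknown event kind '", rec$kind, "'",
           call. = FALSE)
    }
    p <- rec$payload
    ev <- switch(
      rec$kind,
      ADD_LINK = new_event(rec$seq, rec$kind,
                           label = p$finding, label2 = p$hypothesis,
                           polarity = p$polarity %||% "support"),
      MARK_CONFIDENCE = new_event(rec$seq, rec$kind, label = p$item,
                                  mark = p$mark,
                                  item_kind = p$item_kind %||% NA_character_),
      DELETE_ITEM = new_event(rec$seq, rec$kind,
                              label = if (is.character(p)) p else p$item,
                              item_kind = if (is.character(p)) NA_character_
                                          else p$item_kind %||% NA_character_),
      CLOSE_CASE = new_event(rec$seq, rec$kind),
      new_event(rec$seq, rec$kind, label = as.character(p))
    )
    ev$participant <- as.character(rec$participant)
    ev$level <- as.integer(rec$level %||% NA_integer_)
    ev$case <- as.character(rec$case)
    ev$t <- as.character(rec$t %||% NA_character_)
    rows[[i]] <- ev
  }
  sessions_from_events(do.call(rbind, rows))
}

# Assemble a flat event table (participant, level, case, seq, kind, ...)
# into validated per-participant sessions.
sessions_from_events <- function(df) {
  if (is.null(df) || !nrow(df)) {
    return(structure(list(), class = "dxbias_sessions"))
  }
  key <- paste(df$participant, df$case, df$seq, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("session log: duplicate (participant, case, seq) = (",
         d$participant, ", ", d$case, ", ", d$seq, ")", call. = FALSE)
  }
  sessions <- list()
  for (pid in unique(df$participant)) {
    pdf <- df[df$participant == pid, , drop = FALSE]
    lvl <- pdf$level[!is.na(pdf$level)]
    lvl <- if (length(lvl)) lvl[1] else NA_integer_
    records <- list()
    for (cid in unique(pdf$case)) {
      cdf <- pdf[pdf$case == cid,
                 c("seq", "kind", "label", "label2", "polarity", "mark",
                   "item_kind", "t"), drop = FALSE]
      rec <- new_case_record(cid, cdf)
      validate_case_record(rec, pid)
      records[[cid]] <- rec
    }
    sessions[[pid]] <- new_session(pid, lvl, records)
  }
  structure(unname(sessions), class = "dxbias_sessions")
}

validate_case_record <- function(rec, participant = "?") {
  ev <- rec$events
  where <- paste0("participant '", participant, "', case '", rec$case_id, "'")
  if (anyDuplicated(ev$seq)) {
    stop("session log: duplicate seq within ", where, call. = FALSE)
  }
  closes <- which(ev$kind == "CLOSE_CASE")
  if (length(closes) > 1) {
    stop("session log: CLOSE_CASE appears more than once for ", where,
         call. = FALSE)
  }
  if (length(closes) == 1) {
    pre <- ev$kind[seq_len(closes - 1)]
    if (!("ADD_HYPOTHESIS" %in% pre) || !("ADD_DIAGNOSIS" %in% pre)) {
      stop("session log: completed case without a hypothesis and a ",
           "diagnosis before CLOSE_CASE for ", where, call. = FALSE)
    }
    if (any(ev$kind[seq_len(closes - 1)] == "MARK_CONFIDENCE")) {
      stop("session log: MARK_CONFIDENCE before CLOSE_CASE for ", where,
           call. = FALSE)
    }
  } else if (any(ev$kind == "MARK_CONFIDENCE")) {
    stop("session log: MARK_CONFIDENCE in a case never closed for ", where,
         call. = FALSE)
  }
  invisible(rec)
}

#' Evaluate a session against the knowledge base and case truth
#'
#' Replays each case's event stream: every `ADD_FINDING` is correct iff its
#' label is among the case's true findings; every `ADD_HYPOTHESIS` /
#' `ADD_DIAGNOSIS` is correct iff its label is in the acceptable diagnosis
#' set. The final differential is the set of diagnoses added and not deleted
#' before `CLOSE_CASE`, and is classified with [classify_diagnosis()].
#'
#' @param session a single session from [parse_session_log()].
#' @param kb a [knowledge_base()].
#' @param cases a [load_cases()] table resolving every `case_id`.
#' @return A list of evaluated cases, each with the annotated event stream
#'   (`verdict` column), live `final_dx` and `final_findings`, the
#'   `dx_verdict`, and the confidence marks.
#' @export
evaluate_session <- function(session, kb, cases) {
  stopifnot(inherits(session, "dxbias_session"))
  out <- lapply(session$cases, function(rec) {
    cd <- case_def(cases, rec$case_id)
    evaluate_case(rec, cd)
  })
  names(out) <- vapply(session$cases, `[[`, "", "case_id")
  out
}

evaluate_case <- function(rec, cd) {
  ev <- rec$events
  verdict <- rep(NA_character_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    verdict[i] <- switch(
      ev$kind[i],
      ADD_FINDING = if (ev$label[i] %in% cd$true_findings) "correct"
                    else "incorrect",
      ADD_HYPOTHESIS = ,
      ADD_DIAGNOSIS = if (ev$label[i] %in% cd$acceptable_dx) "correct"
                      else "incorrect",
      NA_character_
    )
  }
  ev$verdict <- verdict
  close_i <- which(ev$kind == "CLOSE_CASE")
  upto <- if (length(close_i)) close_i - 1 else nrow(ev)
  live <- replay_live(ev[seq_len(upto), , drop = FALSE])
  final_dx <- live$diagnoses
  conf <- ev[ev$kind == "MARK_CONFIDENCE", c("label", "item_kind", "mark")]
  names(conf)[1] <- "item"
  rownames(conf) <- NULL
  dx_verdict <- if (rec$completed && length(final_dx)) {
    classify_diagnosis(cd, final_dx)
  } else {
    NA_character_
  }
  structure(
    list(case_id = rec$case_id, subdomain = cd$subdomain, events = ev,
         completed = rec$completed, final_dx = final_dx,
         final_findings = live$findings, dx_verdict = dx_verdict,
         confidence = conf, case_def = cd),
    class = "dxbias_evaluated_case"
  )
}

# Forward replay of add/delete events; returns the live entity sets.
replay_live <- function(ev) {
  findings <- character()
  hypotheses <- character()
  diagnoses <- character()
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    lab <- ev$label[i]
    if (k == "ADD_FINDING") findings <- union(findings, lab)
    else if (k == "ADD_HYPOTHESIS") hypotheses <- union(hypotheses, lab)
    else if (k == "ADD_DIAGNOSIS") diagnoses <- union(diagnoses, lab)
    else if (k == "DELETE_ITEM") {
      ik <- ev$item_kind[i]
      if (is.na(ik)) {
        findings <- setdiff(findings, lab)
        hypotheses <- setdiff(hypotheses, lab)
        diagnoses <- setdiff(diagnoses, lab)
      } else if (ik == "finding") findings <- setdiff(findings, lab)
      else if (ik == "hypothesis") hypotheses <- setdiff(hypotheses, lab)
      else if (ik == "diagnosis") diagnoses <- setdiff(diagnoses, lab)
    }
  }
  list(findings = findings, hypotheses = hypotheses, diagnoses = diagnoses)
}

#' Write sessions to a JSONL log
#'
#' Inverse of [parse_session_log()]: one event object per line.
#'
#' @param sessions a `dxbias_sessions` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in sessions) {
    for (rec in s$cases) {
      ev <- rec$events
      for (i in seq_len(nrow(ev))) {
        payload <- switch(
          ev$kind[i],
          ADD_LINK = list(finding = ev$label[i], hypothesis = ev$label2[i],
                          polarity = ev$polarity[i]),
          MARK_CONFIDENCE = list(item = ev$label[i], mark = ev$mark[i],
                                 item_kind = ev$item_kind[i]),
          DELETE_ITEM = list(item = ev$label[i], item_kind = ev$item_kind[i]),
          CLOSE_CASE = NULL,
          ev$label[i]
        )
        obj <- list(participant = s$participant, level = s$level,
                    case = rec$case_id, seq = ev$seq[i], kind = ev$kind[i],
                    payload = payload)
        if (!is.na(ev$t[i])) obj$t <- ev$t[i]
        writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"),
                   con)
      }
    }
  }
  invisible(path)
}

#' @export
print.dxbias_sessions <- function(x, ...) {
  n_cases <- sum(vapply(x, function(s) length(s$cases), 0L))
  cat("<dxbias sessions> ", length(x), " participant(s), ", n_cases,
      " case record(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
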