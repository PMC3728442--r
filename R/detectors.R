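#' @title Rule-based heuristic and bias detectors
#' @description Eight deterministic production rules over evaluated
#'   sessions. Anchoring and representativeness distinguish appropriate use
#'   (heuristic, the shortcut led to a correct diagnosis) from bias
#'   (it led to an incorrect one); availability, confirmation, gambler's
#'   fallacy and search satisficing are detected as biases only. A case is
#'   labelled at most once per rule no matter how many episodes fire, and a
#'   case may carry several labels. `DELETE_ITEM` and `MARK_CONFIDENCE`
#'   events are transparent to every sequence rule.
#' @name detectors
NULL

BIAS_LABELS <- c("ANCHOR_HEURISTIC", "ANCHOR_BIAS", "AVAILABILITY_BIAS",
                 "CONFIRMATION_BIAS", "GAMBLERS_BIAS", "REPR_HEURISTIC",
                 "REPR_BIAS", "SATISFICING_BIAS")

# labels that count as biases / heuristics for error association
BIAS_ONLY_LABELS <- c("ANCHOR_BIAS", "AVAILABILITY_BIAS", "CONFIRMATION_BIAS",
                      "GAMBLERS_BIAS", "REPR_BIAS", "SATISFICING_BIAS")
HEURISTIC_LABELS <- c("ANCHOR_HEURISTIC", "REPR_HEURISTIC")

add_events <- function(ev) ev[ev$kind %in% ADD_KINDS, , drop = FALSE]

#' Detect anchoring in a single evaluated case
#'
#' An anchoring episode starts at a hypothesis entered before (some of) the
#' findings: the participant locked on to an initial impression before
#' examining the evidence. The episode's findings are every finding added
#' after that hypothesis in the case, and each diagnosis entered after at
#' least one of those findings closes an episode. If the diagnosis is
#' supported by all episode findings the episode is the anchoring
#' *heuristic* (whether equal to the hypothesis — sufficient nonadjustment —
#' or not — sufficient adjustment). If it is not so supported and no later
#' hypothesis or diagnosis in the case names a diagnosis supported by all
#' episode findings, the episode is the anchoring *bias* (insufficient
#' adjustment). The case carries the union over episodes.
#'
#' @param ec an evaluated case from [evaluate_session()].
#' @param kb a [knowledge_base()].
#' @return A list with `labels` (subset of `"ANCHOR_HEURISTIC"`,
#'   `"ANCHOR_BIAS"`) and `evidence` (seq numbers per label).
#' @export
detect_anchoring <- function(ec, kb) {
  ev <- ec$events
  labels <- character()
  evidence <- list()
  hyp_i <- which(ev$kind == "ADD_HYPOTHESIS")
  for (h in hyp_i) {
    f_after <- which(ev$kind == "ADD_FINDING" & seq_len(nrow(ev)) > h)
    if (!length(f_after)) next
    ep_findings <- unique(ev$label[f_after])
    dx_after <- which(ev$kind == "ADD_DIAGNOSIS" &
                        seq_len(nrow(ev)) > min(f_after))
    for (d in dx_after) {
      dx <- ev$label[d]
      if (supported_by_all(kb, ep_findings, dx)) {
        labels <- union(labels, "ANCHOR_HEURISTIC")
        evidence$ANCHOR_HEURISTIC <-
          union(evidence$ANCHOR_HEURISTIC, ev$seq[c(h, f_after, d)])
      } else {
        later <- which(ev$kind %in% c("ADD_HYPOTHESIS", "ADD_DIAGNOSIS") &
                         seq_len(nrow(ev)) > d)
        adjusted <- any(vapply(ev$label[later], function(lab)
          supported_by_all(kb, ep_findings, lab), logical(1)))
        if (!adjusted) {
          labels <- union(labels, "ANCHOR_BIAS")
          evidence$ANCHOR_BIAS <-
            union(evidence$ANCHOR_BIAS, ev$seq[c(h, f_after, d)])
        }
      }
    }
  }
  list(labels = labels, evidence = evidence)
}

#' Detect confirmation bias in a single evaluated case
#'
#' Fires when the participant enters an incorrect diagnosis and then
#' identifies a finding that supports it. Under the default strict reading
#' the supporting finding must be the very next diagnostic action; with
#' `window = "any_later"` any subsequent finding in the case qualifies.
#'
#' @inheritParams detect_anchoring
#' @param window `"next"` (default) or `"any_later"`.
#' @return A list with `flag` (logical) and `evidence` (seq numbers).
#' @export
detect_confirmation <- function(ec, kb, window = c("next", "any_later")) {
  window <- match.arg(window)
  ev <- ec$events
  adds <- which(ev$kind %in% ADD_KINDS)
  for (i in which(ev$kind == "ADD_DIAGNOSIS" & ev$verdict == "incorrect")) {
    dx <- ev$label[i]
    later_adds <- adds[adds > i]
    if (!length(later_adds)) next
    cand <- if (window == "next") later_adds[1] else later_adds
    for (j in cand) {
      if (ev$kind[j] == "ADD_FINDING" &&
          supports_quiet(kb, ev$label[j], dx) == "support") {
        return(list(flag = TRUE, evidence = ev$seq[c(i, j)]))
      }
    }
  }
  list(flag = FALSE, evidence = integer())
}

# supports() without vocabulary errors: labels outside the KB never support.
supports_quiet <- function(kb, finding, dx) {
  hit <- kb$relations$finding == finding & kb$relations$diagnosis == dx
  if (!any(hit)) return("none")
  kb$relations$polarity[which(hit)[1]]
}

#' Detect search satisficing in a single evaluated case
#'
#' Premature diagnostic closure: any findings identified precede the
#' hypotheses, a hypothesis is followed by a diagnosis with no intervening
#' finding, the final diagnosis is incorrect or correct-but-incomplete, and
#' the case is closed immediately (no diagnostic action between that
#' diagnosis and `CLOSE_CASE`).
#'
#' @inheritParams detect_anchoring
#' @return A list with `flag` and `evidence` (seq numbers).
#' @export
detect_satisficing <- function(ec) {
  ev <- ec$events
  if (!ec$completed ||
      !isTRUE(ec$dx_verdict %in% c("incorrect", "correct_incomplete"))) {
    return(list(flag = FALSE, evidence = integer()))
  }
  f_i <- which(ev$kind == "ADD_FINDING")
  h_i <- which(ev$kind == "ADD_HYPOTHESIS")
  if (!length(h_i)) return(list(flag = FALSE, evidence = integer()))
  if (length(f_i) && any(f_i > min(h_i))) {
    return(list(flag = FALSE, evidence = integer()))
  }
  adds <- which(ev$kind %in% ADD_KINDS)
  for (h in h_i) {
    for (d in which(ev$kind == "ADD_DIAGNOSIS" & seq_len(nrow(ev)) > h)) {
      if (any(f_i > h & f_i < d)) next
      if (any(adds > d)) next        # not immediately closed
      return(list(flag = TRUE, evidence = ev$seq[c(h, d)]))
    }
  }
  list(flag = FALSE, evidence = integer())
}

#' Detect representativeness across a whole session
#'
#' An occurrence is a finding immediately followed (next diagnostic action)
#' by a diagnosis, where the finding--diagnosis pair belongs to the taught
#' pairs — evidence that the participant is replaying a learned
#' prototype. Pairs occurring more than once anywhere in the session
#' qualify; each qualifying occurrence labels its own case as
#' `REPR_HEURISTIC` when the diagnosis is correct for that case and
#' `REPR_BIAS` when it is incorrect.
#'
#' @param evaluated list of evaluated cases for one session
#'   (from [evaluate_session()]).
#' @param kb a [knowledge_base()].
#' @return Named list (by case id) of lists with `labels` and `evidence`.
#' @export
detect_representativeness <- function(evaluated, kb) {
  occ <- list()   # per (f,d) key: data.frame(case_id, seq_f, seq_d, correct)
  for (ec in evaluated) {
    ev <- ec$events
    adds <- which(ev$kind %in% ADD_KINDS)
    for (pos in seq_along(adds)) {
      i <- adds[pos]
      if (ev$kind[i] != "ADD_FINDING" || pos == length(adds)) next
      j <- adds[pos + 1]
      if (ev$kind[j] != "ADD_DIAGNOSIS") next
      f <- ev$label[i]; d <- ev$label[j]
      if (!is_taught_pair(kb, f, d)) next
      key <- paste(f, d, sep = "\r")
      occ[[key]] <- rbind(occ[[key]], data.frame(
        case_id = ec$case_id, seq_f = ev$seq[i], seq_d = ev$seq[j],
        correct = identical(ev$verdict[j], "correct"),
        stringsAsFactors = FALSE))
    }
  }
  out <- list()
  for (key in names(occ)) {
    o <- occ[[key]]
    if (nrow(o) < 2) next
    for (r in seq_len(nrow(o))) {
      lab <- if (o$correct[r]) "REPR_HEURISTIC" else "REPR_BIAS"
      cid <- o$case_id[r]
      cur <- out[[cid]] %||% list(labels = character(), evidence = list())
      cur$labels <- union(cur$labels, lab)
      cur$evidence[[lab]] <- union(cur$evidence[[lab]],
                                   c(o$seq_f[r], o$seq_d[r]))
      out[[cid]] <- cur
    }
  }
  out
}

#' Detect availability bias on opportunity cases
#'
#' On a designed availability opportunity (two preceding cases of one
#' diagnosis, third case of a disjoint diagnosis), fires when the
#' participant's final diagnosis on the third case is incorrect and names
#' the correct diagnosis of the two predecessors — the recently seen answer
#' came to mind instead of the right one. Both predecessor cases must have
#' been completed by the participant (the case summary shown after each
#' completed case is what exposes the predecessor diagnosis).
#'
#' @param evaluated named list of evaluated cases for one session.
#' @param plan a `dxbias_plan`.
#' @param cases the case-definition table.
#' @return Named list (by case id) of lists with `flag` and `evidence`
#'   (the case-id triple).
#' @export
detect_availability <- function(evaluated, plan, cases) {
  opp <- enumerate_opportunities(plan, cases, "availability")
  out <- list()
  for (cid in opp) {
    ec <- evaluated[[cid]]
    if (is.null(ec) || !ec$completed || is.na(ec$dx_verdict)) next
    pred <- plan_predecessors(plan, cid)
    pre_ok <- all(vapply(pred, function(p) {
      pe <- evaluated[[p]]
      !is.null(pe) && pe$completed
    }, logical(1)))
    if (!pre_ok) next
    shared <- case_def(cases, pred[1])$acceptable_dx
    if (identical(ec$dx_verdict, "incorrect") &&
        length(intersect(ec$final_dx, shared))) {
      out[[cid]] <- list(flag = TRUE, evidence = c(pred, cid))
    }
  }
  out
}

#' Detect gambler's-fallacy bias on opportunity cases
#'
#' On a designed gambler's-fallacy opportunity (three consecutive cases of
#' the same diagnosis), fires when the participant gave the same final
#' differential — correct or not — on the first two cases and then, on the
#' third, a different and incorrect one: the diagnosis was rejected for
#' having appeared too often.
#'
#' @inheritParams detect_availability
#' @return Named list (by case id) of lists with `flag` and `evidence`.
#' @export
detect_gamblers <- function(evaluated, plan, cases) {
  opp <- enumerate_opportunities(plan, cases, "gamblers")
  out <- list()
  for (cid in opp) {
    ec <- evaluated[[cid]]
    if (is.null(ec) || !ec$completed || is.na(ec$dx_verdict)) next
    pred <- plan_predecessors(plan, cid)
    p1 <- evaluated[[pred[1]]]; p2 <- evaluated[[pred[2]]]
    if (is.null(p1) || is.null(p2) || !p1$completed || !p2$completed) next
    if (!setequal(p1$final_dx, p2$final_dx)) next
    if (identical(ec$dx_verdict, "incorrect") &&
        !setequal(ec$final_dx, p1$final_dx)) {
      out[[cid]] <- list(flag = TRUE, evidence = c(pred, cid))
    }
  }
  out
}

#' Run every detector over a set of sessions
#'
#' Evaluates each session against the knowledge base and case truth, applies
#' the eight rules, and collects one row per (participant, case, label)
#' with its triggering evidence.
#'
#' @param sessions a `dxbias_sessions` object.
#' @param kb a [knowledge_base()].
#' @param plan a `dxbias_plan` (sequence context for availability and
#'   gambler's fallacy).
#' @param cases the case-definition table.
#' @param confirmation_window passed to [detect_confirmation()].
#' @return A `dxbias_report`: list with `detections` (data.frame
#'   `participant`, `case_id`, `label`, `evidence`), `evaluated` (per
#'   participant), `levels`, `plan`, and `cases`.
#' @export
detect_all <- function(sessions, kb, plan, cases,
                       confirmation_window = c("next", "any_later")) {
  confirmation_window <- match.arg(confirmation_window)
  stopifnot(inherits(sessions, "dxbias_sessions"))
  rows <- list()
  evaluated_all <- list()
  levels <- data.frame(participant = character(), level = integer(),
                       stringsAsFactors = FALSE)
  emit <- function(pid, cid, label, evidence) {
    rows[[length(rows) + 1]] <<- data.frame(
      participant = pid, case_id = cid, label = label,
      evidence = paste(evidence, collapse = ","), stringsAsFactors = FALSE)
  }
  for (s in sessions) {
    pid <- s$participant
    evaluated <- evaluate_session(s, kb, cases)
    evaluated_all[[pid]] <- evaluated
    levels <- rbind(levels, data.frame(participant = pid, level = s$level,
                                       stringsAsFactors = FALSE))
    for (ec in evaluated) {
      if (!ec$completed) next
      anc <- detect_anchoring(ec, kb)
      for (lab in anc$labels) emit(pid, ec$case_id, lab, anc$evidence[[lab]])
      conf <- detect_confirmation(ec, kb, confirmation_window)
      if (conf$flag) emit(pid, ec$case_id, "CONFIRMATION_BIAS", conf$evidence)
      sat <- detect_satisficing(ec)
      if (sat$flag) emit(pid, ec$case_id, "SATISFICING_BIAS", sat$evidence)
    }
    repr <- detect_representativeness(
      Filter(function(ec) ec$completed, evaluated), kb)
    for (cid in names(repr)) {
      for (lab in repr[[cid]]$labels) {
        emit(pid, cid, lab, repr[[cid]]$evidence[[lab]])
      }
    }
    av <- detect_availability(evaluated, plan, cases)
    for (cid in names(av)) {
      emit(pid, cid, "AVAILABILITY_BIAS", av[[cid]]$evidence)
    }
    gb <- detect_gamblers(evaluated, plan, cases)
    for (cid in names(gb)) {
      emit(pid, cid, "GAMBLERS_BIAS", gb[[cid]]$evidence)
    }
  }
  detections <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(), case_id = character(),
               label = character(), evidence = character(),
               stringsAsFactors = FALSE)
  structure(list(detections = detections, evaluated = evaluated_all,
                 levels = levels, plan = plan, cases = cases,
                 confirmation_window = confirmation_window),
            class = "dxbias_report")
}

#' @export
print.dxbias_report <- function(x, ...) {
  cat("<dxbias detection report> ", nrow(x$levels), " participant(s), ",
      nrow(x$detections), " label(s)\n", sep = "")
  if (nrow(x$detections)) {
    print(table(x$detections$label))
  }
  invisible(x)
}

#' Write a detection report to CSV
#'
#' Columns: participant, case, label, evidence.
#'
#' @param report a `dxbias_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- report$detections
  names(df) <- c("participant", "case", "label", "evidence")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
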