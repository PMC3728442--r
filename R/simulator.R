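#' @title Synthetic clinician simulator
#' @description Agents emit valid per-case event streams over a sequence
#'   plan, optionally injecting bias patterns constructed to satisfy the
#'   detection rules exactly; every injection is recorded as ground truth so
#'   detector recall and false-positive behaviour can be measured without
#'   real participant data.
#' @name simulator
NULL

#' Construct an agent profile
#'
#' Propensities of one simulated participant. `theta` gives, per bias, the
#' probability of emitting that pattern on a case where its preconditions
#' hold. Training level sets the default satisficing and gambler's-fallacy
#' propensities (participants with more training satisfice more in the
#' emulated cohort); every value can be overridden.
#'
#' @param id participant identifier; autogenerated by [simulate_cohort()]
#'   when `NULL`.
#' @param level training level, 1 (junior residents), 2 (senior residents),
#'   or 3 (fellows/attendings).
#' @param p_find probability of identifying each true finding.
#' @param p_dx probability of a correct (and complete) diagnosis when no
#'   bias fires.
#' @param theta named numeric vector/list over
#'   `c("satisficing", "availability", "gamblers", "confirmation",
#'   "anchor_bias", "representativeness_bias")`; omitted entries take the
#'   level defaults.
#' @param p_sure_given_correct probability of marking a correct item `sure`.
#' @param p_sure_given_incorrect probability of marking an incorrect item
#'   `sure`.
#' @return An object of class `dxbias_agent`.
#' @export
agent_profile <- function(id = NULL, level = 1, p_find = 0.7, p_dx = 0.32,
                          theta = list(),
                          p_sure_given_correct = 0.75,
                          p_sure_given_incorrect = 0.45) {
  level <- as.integer(level)
  stopifnot(level %in% 1:3)
  defaults <- list(
    satisficing = c(0.14, 0.27, 0.30)[level],
    availability = 0.20,
    gamblers = c(0.04, 0.10, 0.10)[level],
    confirmation = 0.01,
    anchor_bias = 0.06,
    representativeness_bias = 0.02
  )
  theta <- utils::modifyList(defaults, as.list(theta))
  unknown <- setdiff(names(theta), names(defaults))
  if (length(unknown)) {
    stop("agent_profile: unknown theta component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  probs <- c(unlist(theta), p_find = p_find, p_dx = p_dx,
             psc = p_sure_given_correct, psi = p_sure_given_incorrect)
  if (any(probs < 0 | probs > 1)) {
    stop("agent_profile: all probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(id = id, level = level, p_find = p_find, p_dx = p_dx,
                 theta = theta,
                 p_sure_given_correct = p_sure_given_correct,
                 p_sure_given_incorrect = p_sure_given_incorrect),
            class = "dxbias_agent")
}

#' Load agent profiles from YAML
#'
#' The file holds a list of profile entries with the [agent_profile()]
#' fields (`id`, `level`, `p_find`, `p_dx`, `theta`, ...).
#'
#' @param path path to a YAML (or JSON) file.
#' @return List of `dxbias_agent` objects.
#' @export
load_profiles <- function(path) {
  raw <- read_structured(path)
  lapply(raw, function(r) do.call(agent_profile, r))
}

# injection priority: first feasible bias that draws under its theta wins;
# sequence biases are attempted only on their own opportunity cases and
# case-level biases only off them, so truth labels stay unambiguous.
INJECTION_PRIORITY <- c("satisficing", "availability", "gamblers",
                        "confirmation", "anchor_bias",
                        "representativeness_bias")

TRUTH_LABEL <- c(satisficing = "SATISFICING_BIAS",
                 availability = "AVAILABILITY_BIAS",
                 gamblers = "GAMBLERS_BIAS",
                 confirmation = "CONFIRMATION_BIAS",
                 anchor_bias = "ANCHOR_BIAS",
                 representativeness_bias = "REPR_BIAS")

#' Simulate a cohort of sessions over a plan
#'
#' Each agent works both sub-domain sequences in plan order, completing
#' every case. Per case, at most one bias pattern is injected (priority
#' order satisficing, availability, gambler's fallacy, confirmation,
#' anchoring, representativeness; availability and gambler's patterns only
#' on their opportunity cases, the others only off them). When no bias
#' fires the agent emits a default stream: true findings in canonical order
#' (each identified with probability `p_find`), a hypothesis, and the final
#' diagnosis — the full acceptable set with probability `p_dx`, otherwise a
#' wrong diagnosis followed by a competing hypothesis before closing.
#' Confidence marks follow `CLOSE_CASE` for every live finding and
#' diagnosis. One pseudo-random stream per participant, seeded
#' `seed + participant index`, keeps cohorts stable under reordering.
#'
#' @param profiles list of [agent_profile()] objects.
#' @param plan a `dxbias_plan`.
#' @param cases the case-definition table.
#' @param kb a [knowledge_base()].
#' @param seed integer seed.
#' @return A `dxbias_cohort`: list with `sessions` (a `dxbias_sessions`)
#'   and `truth` (data.frame participant, case_id, label of every injected,
#'   detectable pattern).
#' @export
simulate_cohort <- function(profiles, plan, cases, kb, seed = 1) {
  stopifnot(inherits(plan, "dxbias_plan"), inherits(kb, "dxbias_kb"))
  profiles <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    stopifnot(inherits(p, "dxbias_agent"))
    if (is.null(p$id)) p$id <- sprintf("sim%03d", i)
    p
  })
  opp_avail <- enumerate_opportunities(plan, cases, "availability")
  opp_gamb  <- enumerate_opportunities(plan, cases, "gamblers")
  sessions <- list()
  truth <- list()
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    res <- with_seed(seed + i, simulate_session(prof, plan, cases, kb,
                                                opp_avail, opp_gamb))
    sessions[[prof$id]] <- res$session
    truth[[prof$id]] <- res$truth
  }
  truth <- do.call(rbind, c(truth, list(
    data.frame(participant = character(), case_id = character(),
               label = character(), stringsAsFactors = FALSE))))
  rownames(truth) <- NULL
  structure(list(sessions = structure(unname(sessions),
                                      class = "dxbias_sessions"),
                 truth = truth),
            class = "dxbias_cohort")
}

simulate_session <- function(prof, plan, cases, kb, opp_avail, opp_gamb) {
  records <- list()
  truth_rows <- list()
  repr_pair <- NULL
  if (nrow(kb$taught_pairs)) {
    j <- sample.int(nrow(kb$taught_pairs), 1)
    repr_pair <- list(finding = kb$taught_pairs$finding[j],
                      dx = kb$taught_pairs$diagnosis[j])
  }
  repr_cases <- character()
  final_by_case <- list()
  for (sd in names(plan)) {
    for (cid in plan[[sd]]) {
      cd <- case_def(cases, cid)
      kind <- choose_injection(prof, cd, cid, kb, plan,
                               opp_avail, opp_gamb, final_by_case, repr_pair)
      ev <- emit_case_stream(prof, cd, kb, kind, plan, cases,
                             final_by_case, repr_pair)
      rec <- new_case_record(cid, ev)
      records[[cid]] <- rec
      final_by_case[[cid]] <- replay_live(
        ev[ev$kind != "MARK_CONFIDENCE" & ev$kind != "CLOSE_CASE", ,
           drop = FALSE])$diagnoses
      if (!is.null(kind)) {
        if (kind == "representativeness_bias") {
          repr_cases <- c(repr_cases, cid)
        } else {
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            participant = prof$id, case_id = cid,
            label = TRUTH_LABEL[[kind]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  # a single taught-pair occurrence is undetectable by definition; only
  # sessions with a repeated pair yield guaranteed representativeness labels
  if (length(repr_cases) >= 2) {
    for (cid in repr_cases) {
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        participant = prof$id, case_id = cid, label = "REPR_BIAS",
        stringsAsFactors = FALSE)
    }
  }
  list(session = new_session(prof$id, prof$level, records),
       truth = do.call(rbind, c(truth_rows, list(
         data.frame(participant = character(), case_id = character(),
                    label = character(), stringsAsFactors = FALSE)))))
}

choose_injection <- function(prof, cd, cid, kb, plan, opp_avail, opp_gamb,
                             final_by_case, repr_pair) {
  is_avail <- cid %in% opp_avail
  is_gamb <- cid %in% opp_gamb
  for (bias in INJECTION_PRIORITY) {
    feasible <- switch(
      bias,
      satisficing = !is_avail && !is_gamb &&
        length(wrong_dx_pool(kb, cd)) > 0,
      availability = is_avail,
      gamblers = {
        if (!is_gamb) FALSE else {
          pred <- plan_predecessors(plan, cid)
          p1 <- final_by_case[[pred[1]]]; p2 <- final_by_case[[pred[2]]]
          !is.null(p1) && !is.null(p2) && setequal(p1, p2) &&
            length(setdiff(wrong_dx_pool(kb, cd), p1)) > 0
        }
      },
      confirmation = !is_avail && !is_gamb &&
        length(confirmable_dx(kb, cd)) > 0,
      anchor_bias = !is_avail && !is_gamb &&
        !is.null(anchor_bias_material(kb, cd)),
      representativeness_bias = !is_avail && !is_gamb &&
        !is.null(repr_pair) && !(repr_pair$dx %in% cd$acceptable_dx)
    )
    if (feasible && stats::runif(1) < prof$theta[[bias]]) return(bias)
  }
  NULL
}

wrong_dx_pool <- function(kb, cd) setdiff(kb$diagnoses, cd$acceptable_dx)

# wrong diagnoses that have at least one supporting finding in the KB
confirmable_dx <- function(kb, cd) {
  pool <- wrong_dx_pool(kb, cd)
  sup <- kb$relations[kb$relations$polarity == "support", ]
  intersect(pool, unique(sup$diagnosis))
}

# a (finding, wrong diagnosis) pair with no support edge, or NULL
anchor_bias_material <- function(kb, cd) {
  for (d in wrong_dx_pool(kb, cd)) {
    sup <- kb$relations$finding[kb$relations$polarity == "support" &
                                  kb$relations$diagnosis == d]
    f <- setdiff(cd$true_findings, sup)
    if (!length(f)) f <- setdiff(kb$findings, sup)
    if (length(f)) return(list(finding = f[1], dx = d))
  }
  NULL
}

emit_case_stream <- function(prof, cd, kb, kind, plan, cases,
                             final_by_case, repr_pair) {
  s <- 0L
  ev <- list()
  push <- function(kind_, label = NA_character_, label2 = NA_character_,
                   mark = NA_character_, item_kind = NA_character_) {
    s <<- s + 1L
    ev[[length(ev) + 1]] <<- new_event(s, kind_, label = label,
                                       label2 = label2, mark = mark,
                                       item_kind = item_kind)
  }
  found <- cd$true_findings[stats::runif(length(cd$true_findings)) <
                              prof$p_find]
  pick1 <- function(x) x[sample.int(length(x), 1)]

  if (is.null(kind)) {
    for (f in found) push("ADD_FINDING", f)
    if (stats::runif(1) < prof$p_dx) {
      push("ADD_HYPOTHESIS", cd$acceptable_dx[1])
      for (d in cd$acceptable_dx) push("ADD_DIAGNOSIS", d)
    } else {
      w <- pick1(wrong_dx_pool(kb, cd))
      push("ADD_HYPOTHESIS", w)
      push("ADD_DIAGNOSIS", w)
      push("ADD_HYPOTHESIS", pick1(setdiff(kb$diagnoses, w)))
    }
  } else if (kind == "satisficing") {
    for (f in found) push("ADD_FINDING", f)
    w <- pick1(wrong_dx_pool(kb, cd))
    push("ADD_HYPOTHESIS", w)
    push("ADD_DIAGNOSIS", w)
  } else if (kind %in% c("availability", "gamblers")) {
    pred <- plan_predecessors(plan, cd$case_id)
    w <- if (kind == "availability") {
      pick1(case_def(cases, pred[1])$acceptable_dx)
    } else {
      pick1(setdiff(wrong_dx_pool(kb, cd), final_by_case[[pred[1]]]))
    }
    for (f in found) push("ADD_FINDING", f)
    push("ADD_HYPOTHESIS", w)
    push("ADD_DIAGNOSIS", w)
    push("ADD_HYPOTHESIS", pick1(setdiff(kb$diagnoses, w)))
  } else if (kind == "confirmation") {
    w <- pick1(confirmable_dx(kb, cd))
    sup <- kb$relations$finding[kb$relations$polarity == "support" &
                                  kb$relations$diagnosis == w]
    push("ADD_DIAGNOSIS", w)
    push("ADD_FINDING", pick1(sup))
    push("ADD_HYPOTHESIS", pick1(setdiff(kb$diagnoses, w)))
  } else if (kind == "anchor_bias") {
    m <- anchor_bias_material(kb, cd)
    push("ADD_HYPOTHESIS", m$dx)
    push("ADD_FINDING", m$finding)
    push("ADD_DIAGNOSIS", m$dx)
  } else if (kind == "representativeness_bias") {
    push("ADD_FINDING", repr_pair$finding)
    push("ADD_DIAGNOSIS", repr_pair$dx)
    push("ADD_HYPOTHESIS", pick1(setdiff(kb$diagnoses, repr_pair$dx)))
  }
  push("CLOSE_CASE")

  events <- do.call(rbind, ev)
  live <- replay_live(events)
  for (f in live$findings) {
    p <- if (f %in% cd$true_findings) prof$p_sure_given_correct
         else prof$p_sure_given_incorrect
    push("MARK_CONFIDENCE", f, mark = if (stats::runif(1) < p) "sure"
                                      else "unsure", item_kind = "finding")
  }
  for (d in live$diagnoses) {
    p <- if (d %in% cd$acceptable_dx) prof$p_sure_given_correct
         else prof$p_sure_given_incorrect
    push("MARK_CONFIDENCE", d, mark = if (stats::runif(1) < p) "sure"
                                      else "unsure", item_kind = "diagnosis")
  }
  do.call(rbind, ev)
}

#' Write a cohort's ground-truth labels to CSV
#' @param cohort a `dxbias_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(cohort, path) {
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dxbias_cohort <- function(x, ...) {
  cat("<dxbias simulated cohort> ", length(x$sessions),
      " session(s), ", nrow(x$truth), " injected label(s)\n", sep = "")
  invisible(x)
}
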