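#' Feeling-of-knowing bias score for one case
#'
#' After concluding a case the participant marks each identified item as
#' `sure` or `unsure`; the system judges each item correct or incorrect.
#' The scoreable items are the identified findings and diagnoses live at
#' case close (hypotheses and relationship links, though markable, are
#' excluded), weighted equally. The score is
#' `(total_sure - total_correct) / total_items`, ranging from +1
#' (completely overconfident: sure of everything, right about nothing)
#' through 0 (confidence matches performance in the totals) to -1
#' (completely underconfident).
#'
#' @param ec an evaluated case from [evaluate_session()]; must be completed.
#' @return A list with `case_id`, `total_sure`, `total_correct`,
#'   `total_items`, and `score`.
#' @export
case_bias_score <- function(ec) {
  stopifnot(inherits(ec, "dxbias_evaluated_case"))
  if (!ec$completed) {
    stop("case_bias_score: case '", ec$case_id, "' was not completed",
         call. = FALSE)
  }
  items <- data.frame(
    item = c(ec$final_findings, ec$final_dx),
    item_kind = c(rep("finding", length(ec$final_findings)),
                  rep("diagnosis", length(ec$final_dx))),
    stringsAsFactors = FALSE
  )
  if (!nrow(items)) {
    stop("case_bias_score: case '", ec$case_id,
         "' has no scoreable items (no identified findings or diagnoses)",
         call. = FALSE)
  }
  cd <- ec$case_def
  items$correct <- ifelse(items$item_kind == "finding",
                          items$item %in% cd$true_findings,
                          items$item %in% cd$acceptable_dx)
  conf <- ec$confidence
  items$mark <- vapply(seq_len(nrow(items)), function(i) {
    hit <- conf$item == items$item[i] &
      (is.na(conf$item_kind) | conf$item_kind == items$item_kind[i])
    if (any(hit)) conf$mark[which(hit)[1]] else NA_character_
  }, "")
  if (anyNA(items$mark)) {
    warning("case '", ec$case_id, "': ", sum(is.na(items$mark)),
            " scoreable item(s) without a confidence mark, treated as ",
            "unsure", call. = FALSE)
    items$mark[is.na(items$mark)] <- "unsure"
  }
  total_sure <- sum(items$mark == "sure")
  total_correct <- sum(items$correct)
  total_items <- nrow(items)
  list(case_id = ec$case_id,
       total_sure = total_sure,
       total_correct = total_correct,
       total_items = total_items,
       score = (total_sure - total_correct) / total_items)
}

#' Average bias score for one participant
#'
#' @param evaluated list of evaluated cases for one session.
#' @param weight `"case"` (default; unweighted mean of case scores) or
#'   `"item"` (pools the totals across cases, weighting each case by its
#'   item count).
#' @return A single number in `[-1, +1]`.
#' @export
participant_bias_score <- function(evaluated, weight = c("case", "item")) {
  weight <- match.arg(weight)
  scoreable <- Filter(function(ec) {
    ec$completed && (length(ec$final_findings) + length(ec$final_dx)) > 0
  }, evaluated)
  if (!length(scoreable)) {
    stop("participant_bias_score: no completed scoreable cases",
         call. = FALSE)
  }
  scores <- lapply(scoreable, case_bias_score)
  if (weight == "case") {
    mean(vapply(scores, `[[`, 0, "score"))
  } else {
    sure  <- sum(vapply(scores, `[[`, 0, "total_sure"))
    corr  <- sum(vapply(scores, `[[`, 0, "total_correct"))
    items <- sum(vapply(scores, `[[`, 0, "total_items"))
    (sure - corr) / items
  }
}

#' Per-case confidence table for a report
#'
#' One row per completed scoreable case with the bias-score components, for
#' inclusion in summary output.
#'
#' @param report a `dxbias_report` from [detect_all()].
#' @return data.frame with columns participant, case, total_sure,
#'   total_correct, total_items, bias_score.
#' @export
confidence_table <- function(report) {
  rows <- list()
  for (pid in names(report$evaluated)) {
    for (ec in report$evaluated[[pid]]) {
      if (!ec$completed ||
          (length(ec$final_findings) + length(ec$final_dx)) == 0) next
      s <- case_bias_score(ec)
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid, case = s$case_id, total_sure = s$total_sure,
        total_correct = s$total_correct, total_items = s$total_items,
        bias_score = s$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(participant = character(), case = character(),
                      total_sure = integer(), total_correct = integer(),
                      total_items = integer(), bias_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
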