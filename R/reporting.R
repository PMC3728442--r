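#' Per-participant frequency table with opportunity-aware denominators
#'
#' For each participant and label, counts flagged cases against the number
#' of completed cases in which the label could occur: all completed cases
#' for the case-level rules (anchoring, confirmation, representativeness,
#' satisficing), and only completed opportunity cases whose two plan
#' predecessors were also completed for availability and gambler's fallacy.
#' Percentages are reported to one decimal place; a zero denominator yields
#' a missing percent.
#'
#' @param report a `dxbias_report` from [detect_all()].
#' @return data.frame with columns participant, level, label, n_cases,
#'   n_possible, percent.
#' @export
frequency_table <- function(report) {
  stopifnot(inherits(report, "dxbias_report"))
  plan <- report$plan
  cases <- report$cases
  opp <- list(
    AVAILABILITY_BIAS = enumerate_opportunities(plan, cases, "availability"),
    GAMBLERS_BIAS = enumerate_opportunities(plan, cases, "gamblers")
  )
  det <- report$detections
  rows <- list()
  for (pid in names(report$evaluated)) {
    evaluated <- report$evaluated[[pid]]
    completed <- names(Filter(function(ec) ec$completed, evaluated))
    lvl <- report$levels$level[match(pid, report$levels$participant)]
    for (lab in BIAS_LABELS) {
      denom <- if (lab %in% names(opp)) {
        sum(vapply(opp[[lab]], function(cid) {
          pred <- plan_predecessors(plan, cid)
          cid %in% completed && all(pred %in% completed)
        }, logical(1)))
      } else {
        length(completed)
      }
      n <- sum(det$participant == pid & det$label == lab)
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid, level = lvl, label = lab, n_cases = n,
        n_possible = denom,
        percent = if (denom > 0) round(100 * n / denom, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and SD-from-median summaries of a frequency table
#'
#' The dispersion reported alongside medians for these non-normal counts is
#' the root-mean-square deviation about the median.
#'
#' @param freqs output of [frequency_table()].
#' @param by `"all"` for a pooled summary or `"level"` for one per training
#'   level.
#' @param value which column to summarize: `"percent"` or `"n_cases"`.
#' @return data.frame with label, group, median, sd_from_median, n.
#' @export
summarize_frequencies <- function(freqs, by = c("all", "level"),
                                  value = c("percent", "n_cases")) {
  by <- match.arg(by)
  value <- match.arg(value)
  groups <- if (by == "all") list(all = freqs) else
    split(freqs, freqs$level)
  rows <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    for (lab in unique(df$label)) {
      x <- df[[value]][df$label == lab]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, group = g,
        median = if (length(x)) stats::median(x) else NA_real_,
        sd_from_median = sd_from_median(x),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sd_from_median <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - stats::median(x))^2))
}

#' Error--bias association summary
#'
#' Among completed cases with an incorrect final diagnosis, the percentage
#' carrying at least one bias label; among completed correctly diagnosed
#' cases, the percentage carrying at least one heuristic label. Per-label
#' breakdowns are normalized for opportunity: availability and gambler's
#' fallacy are computed over error (or correct) cases that were opportunity
#' cases with completed predecessors; with
#' `opportunity_denominator = "all_opportunities"` the per-label denominator
#' is instead every completed opportunity case.
#'
#' @param report a `dxbias_report`.
#' @param opportunity_denominator `"error_opportunities"` (default) or
#'   `"all_opportunities"`.
#' @return A list with `pct_error_cases`, `pct_error_with_bias`,
#'   `pct_correct_with_heuristic`, and `per_label` (data.frame label,
#'   n_flagged, n_possible, percent).
#' @export
error_bias_association <- function(report,
                                   opportunity_denominator =
                                     c("error_opportunities",
                                       "all_opportunities")) {
  opportunity_denominator <- match.arg(opportunity_denominator)
  plan <- report$plan
  cases <- report$cases
  det <- report$detections
  opp <- list(
    AVAILABILITY_BIAS = enumerate_opportunities(plan, cases, "availability"),
    GAMBLERS_BIAS = enumerate_opportunities(plan, cases, "gamblers")
  )
  rows <- list()
  for (pid in names(report$evaluated)) {
    for (ec in report$evaluated[[pid]]) {
      if (!ec$completed || is.na(ec$dx_verdict)) next
      labs <- det$label[det$participant == pid & det$case_id == ec$case_id]
      completed <- names(Filter(function(e) e$completed,
                                report$evaluated[[pid]]))
      is_opp <- vapply(names(opp), function(ol) {
        ec$case_id %in% opp[[ol]] &&
          all(plan_predecessors(plan, ec$case_id) %in% completed)
      }, logical(1))
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid, case_id = ec$case_id,
        error = identical(ec$dx_verdict, "incorrect"),
        any_bias = any(labs %in% BIAS_ONLY_LABELS),
        any_heuristic = any(labs %in% HEURISTIC_LABELS),
        ANCHOR_BIAS = "ANCHOR_BIAS" %in% labs,
        AVAILABILITY_BIAS = "AVAILABILITY_BIAS" %in% labs,
        CONFIRMATION_BIAS = "CONFIRMATION_BIAS" %in% labs,
        GAMBLERS_BIAS = "GAMBLERS_BIAS" %in% labs,
        REPR_BIAS = "REPR_BIAS" %in% labs,
        SATISFICING_BIAS = "SATISFICING_BIAS" %in% labs,
        opp_avail = is_opp[["AVAILABILITY_BIAS"]],
        opp_gamb = is_opp[["GAMBLERS_BIAS"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("error_bias_association: no completed cases",
                          call. = FALSE)
  tab <- do.call(rbind, rows)
  err <- tab[tab$error, , drop = FALSE]
  cor <- tab[!tab$error, , drop = FALSE]
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1)
                            else NA_real_
  per_label <- do.call(rbind, lapply(BIAS_ONLY_LABELS, function(lab) {
    den_tab <- err
    if (lab == "AVAILABILITY_BIAS") {
      den_tab <- if (opportunity_denominator == "error_opportunities")
        err[err$opp_avail, , drop = FALSE] else tab[tab$opp_avail, ,
                                                    drop = FALSE]
    } else if (lab == "GAMBLERS_BIAS") {
      den_tab <- if (opportunity_denominator == "error_opportunities")
        err[err$opp_gamb, , drop = FALSE] else tab[tab$opp_gamb, ,
                                                   drop = FALSE]
    }
    data.frame(label = lab, n_flagged = sum(den_tab[[lab]]),
               n_possible = nrow(den_tab),
               percent = pct(sum(den_tab[[lab]]), nrow(den_tab)),
               stringsAsFactors = FALSE)
  }))
  list(
    n_completed = nrow(tab),
    pct_error_cases = pct(nrow(err), nrow(tab)),
    pct_error_with_bias = pct(sum(err$any_bias), nrow(err)),
    pct_correct_with_heuristic = pct(sum(cor$any_heuristic), nrow(cor)),
    per_label = per_label,
    case_table = tab
  )
}

#' Nonparametric comparison of frequencies across training levels
#'
#' Kruskal--Wallis test across the groups plus pairwise Mann--Whitney
#' (Wilcoxon rank-sum) comparisons with normal-approximation z and effect
#' size r = |z| / sqrt(n). Two-sided; no multiple-testing adjustment is
#' applied, and alpha = 0.05 is reported, not enforced.
#'
#' @param freqs output of [frequency_table()] (or any data.frame with the
#'   value column and a `level` column).
#' @param label which detection label's rows to compare.
#' @param value value column, `"percent"` or `"n_cases"`.
#' @return A list with `kruskal` (statistic H, df, p, eta squared) and
#'   `pairwise` (data.frame group1, group2, U, z, p, r).
#' @export
compare_groups <- function(freqs, label = "SATISFICING_BIAS",
                           value = c("percent", "n_cases")) {
  value <- match.arg(value)
  df <- freqs[freqs$label == label & !is.na(freqs[[value]]), , drop = FALSE]
  groups <- split(df[[value]], df$level)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    stop("compare_groups: need at least two non-empty groups", call. = FALSE)
  }
  kw <- stats::kruskal.test(df[[value]], factor(df$level))
  n <- nrow(df)
  k <- length(groups)
  eta2 <- (unname(kw$statistic) - k + 1) / (n - k)
  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- groups[[pairs[1, j]]]
    g2 <- groups[[pairs[2, j]]]
    mw <- mann_whitney_z(g1, g2)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               U = mw$U, z = mw$z, p = mw$p,
               r = abs(mw$z) / sqrt(length(g1) + length(g2)),
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value, eta2 = eta2),
       pairwise = pw, alpha = 0.05, adjustment = "none")
}

# Mann-Whitney U with tie-corrected normal approximation.
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = FALSE)$p.value)
  list(U = U, z = z, p = p)
}

#' Write the summary tables to CSV
#'
#' Emits the per-participant frequency table joined with the per-case
#' confidence scores' participant means.
#'
#' @param report a `dxbias_report`.
#' @param path output path.
#' @return The combined data.frame, invisibly.
#' @export
write_summary_csv <- function(report, path) {
  freqs <- frequency_table(report)
  conf <- confidence_table(report)
  if (nrow(conf)) {
    means <- stats::aggregate(bias_score ~ participant, conf, mean)
    names(means)[2] <- "mean_bias_score"
    freqs <- merge(freqs, means, by = "participant", all.x = TRUE)
  } else {
    freqs$mean_bias_score <- NA_real_
  }
  utils::write.csv(freqs, path, row.names = FALSE)
  invisible(freqs)
}
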