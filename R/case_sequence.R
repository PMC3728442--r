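#' @title Case-sequence plans and opportunity enumeration
#' @description Availability and gambler's-fallacy biases are sequence
#'   phenomena: they can only occur at designed positions in the case
#'   sequence. A plan is an ordered list of case ids per sub-domain;
#'   opportunity cases are always recomputed from the case truth, never
#'   trusted from file.
#' @name case_sequence
NULL

#' Construct a sequence plan
#'
#' @param sequences named list: sub-domain label -> ordered character vector
#'   of case ids. No case id may repeat within a sub-domain sequence.
#' @return An object of class `dxbias_plan`.
#' @export
sequence_plan <- function(sequences) {
  stopifnot(is.list(sequences), !is.null(names(sequences)))
  for (sd in names(sequences)) {
    s <- as.character(sequences[[sd]])
    if (anyDuplicated(s)) {
      stop("sequence plan: repeated case_id in sub-domain '", sd, "': ",
           paste(unique(s[duplicated(s)]), collapse = ", "), call. = FALSE)
    }
    sequences[[sd]] <- s
  }
  structure(sequences, class = "dxbias_plan")
}

#' Load a sequence plan from JSON
#'
#' The file maps each sub-domain to its ordered case-id array, e.g.
#' `{"SVD": ["svd_01", ...], "NDD": [...]}`.
#'
#' @param path path to a JSON file.
#' @return A `dxbias_plan`.
#' @export
load_plan <- function(path) {
  sequence_plan(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Write a sequence plan to JSON
#' @param plan a `dxbias_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE)
  invisible(path)
}

#' Enumerate opportunity cases in a plan
#'
#' Slides a window of three consecutive cases over each sub-domain sequence
#' independently. The third case of a window is an availability opportunity
#' when the two predecessors share one acceptable-diagnosis set and the
#' third case's set is disjoint from it; it is a gambler's-fallacy
#' opportunity when all three sets are equal. The first two positions of a
#' sequence are never flagged, and the two opportunity sets are disjoint by
#' construction.
#'
#' @param plan a `dxbias_plan`.
#' @param cases a [load_cases()] table resolving every planned case id.
#' @param kind `"availability"` or `"gamblers"`.
#' @return Character vector of flagged case ids (order of appearance).
#' @export
enumerate_opportunities <- function(plan, cases,
                                    kind = c("availability", "gamblers")) {
  kind <- match.arg(kind)
  stopifnot(inherits(plan, "dxbias_plan"))
  out <- character()
  for (sd in names(plan)) {
    seq_ids <- plan[[sd]]
    if (length(seq_ids) < 3) next
    acc <- lapply(seq_ids, function(id) case_def(cases, id)$acceptable_dx)
    for (k in 3:length(seq_ids)) {
      a <- acc[[k - 2]]; b <- acc[[k - 1]]; c_ <- acc[[k]]
      if (!setequal(a, b)) next
      if (kind == "availability") {
        if (!length(intersect(a, c_))) out <- c(out, seq_ids[k])
      } else {
        if (setequal(a, c_)) out <- c(out, seq_ids[k])
      }
    }
  }
  out
}

# For an opportunity case id, the (k-2, k-1) predecessor ids in its
# sub-domain sequence.
plan_predecessors <- function(plan, case_id) {
  for (sd in names(plan)) {
    k <- match(case_id, plan[[sd]])
    if (!is.na(k) && k >= 3) {
      return(plan[[sd]][c(k - 2, k - 1)])
    }
  }
  NULL
}

#' Build the default study plan
#'
#' Lays out, per sub-domain, a 20-case sequence embedding gambler's-fallacy
#' opportunities as runs of identical-diagnosis cases (a run of length r
#' contributes r - 2 sliding-window opportunities) and availability
#' opportunities as a disjoint-diagnosis case appended directly after a
#' two-case (or longer) run. The default study layout yields 5 gambler's
#' and 3 availability opportunity cases per sub-domain — 10 and 6 in total
#' over the two sequences. Remaining positions are padded with cases whose
#' acceptable sets differ from their neighbours', so no further windows
#' qualify. The builder is deterministic given `seed`, which shuffles which
#' diagnosis groups fill which blocks and the padding order.
#'
#' @param cases a [load_cases()] case library with at least `n_cases` cases
#'   per sub-domain, including identical-acceptable-set groups large enough
#'   for the runs.
#' @param seed integer seed.
#' @param n_cases sequence length per sub-domain (default 20).
#' @param n_availability availability opportunities per sub-domain
#'   (default 3).
#' @param n_gamblers gambler's-fallacy opportunities per sub-domain
#'   (default 5).
#' @return A `dxbias_plan` whose [enumerate_opportunities()] counts equal
#'   the requested numbers exactly.
#' @export
build_default_plan <- function(cases, seed = 0, n_cases = 20,
                               n_availability = 3, n_gamblers = 5) {
  stopifnot(inherits(cases, "data.frame"))
  with_seed(seed, {
    plan <- list()
    for (sd in unique(cases$subdomain)) {
      plan[[sd]] <- build_subdomain_sequence(
        cases[cases$subdomain == sd, , drop = FALSE],
        n_cases, n_availability, n_gamblers
      )
    }
    plan <- sequence_plan(plan)
  })
  got_a <- length(enumerate_opportunities(plan, cases, "availability"))
  got_g <- length(enumerate_opportunities(plan, cases, "gamblers"))
  want_a <- n_availability * length(plan)
  want_g <- n_gamblers * length(plan)
  if (got_a != want_a || got_g != want_g) {
    stop("build_default_plan: constructed plan has ", got_a,
         " availability and ", got_g, " gambler's opportunities; expected ",
         want_a, " and ", want_g, call. = FALSE)
  }
  plan
}

# One sub-domain sequence. Run lengths for g opportunities use blocks of at
# most 4 (4 -> 2 opportunities, 3 -> 1); each availability opportunity is a
# disjoint single placed right after a run tail (extra ones, beyond the
# number of runs, become standalone pair+single blocks).
build_subdomain_sequence <- function(sub, n_cases, n_avail, n_gamb) {
  sig <- vapply(sub$acceptable_dx,
                function(a) paste(sort(a), collapse = "\r"), "")
  groups <- split(sub$case_id, sig)
  groups <- groups[order(-lengths(groups))]

  run_lengths <- integer()
  g <- n_gamb
  while (g >= 2) { run_lengths <- c(run_lengths, 4L); g <- g - 2L }
  if (g == 1) run_lengths <- c(run_lengths, 3L)

  extra_avail <- max(0L, n_avail - length(run_lengths))
  run_lengths <- c(run_lengths, rep(2L, extra_avail))
  n_after_run <- min(n_avail, length(run_lengths))

  # assign a distinct diagnosis group to every run, largest runs first
  avail_groups <- groups
  run_groups <- list()
  for (r in seq_along(run_lengths)) {
    ok <- which(lengths(avail_groups) >= run_lengths[r])
    if (!length(ok)) {
      stop("build_default_plan: sub-domain '", sub$subdomain[1],
           "' lacks a diagnosis group with >= ", run_lengths[r],
           " cases sharing one acceptable set", call. = FALSE)
    }
    pick <- ok[sample.int(length(ok), 1)]
    run_groups[[r]] <- avail_groups[[pick]][seq_len(run_lengths[r])]
    avail_groups[[pick]] <- NULL
  }
  singles <- unlist(lapply(avail_groups, `[`, 1), use.names = FALSE)
  singles <- sample(singles, length(singles))
  need_singles <- n_avail + (n_cases - sum(run_lengths) - n_avail)
  if (length(singles) < need_singles) {
    stop("build_default_plan: sub-domain '", sub$subdomain[1], "' needs ",
         need_singles, " cases with pairwise-distinct acceptable sets ",
         "outside the runs, found ", length(singles), call. = FALSE)
  }

  seq_ids <- character()
  si <- 1
  for (r in seq_along(run_lengths)) {
    seq_ids <- c(seq_ids, run_groups[[r]])
    if (r <= n_avail) {            # disjoint single closes the triple
      seq_ids <- c(seq_ids, singles[si]); si <- si + 1
    }
  }
  pad <- singles[seq(si, length.out = n_cases - length(seq_ids))]
  c(seq_ids, pad)
}

#' @export
print.dxbias_plan <- function(x, ...) {
  cat("<dxbias sequence plan>\n")
  for (sd in names(x)) {
    cat("  ", sd, ": ", length(x[[sd]]), " cases\n", sep = "")
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
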