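test_that("frequency denominators follow the completed-opportunity rule", {
  fx <- fixture_report()
  fr <- frequency_table(fx$rep)
  g <- function(p, lab) fr[fr$participant == p & fr$label == lab, ]

  # p1: 6 completed cases, 3 satisficing flags -> 50.0%
  expect_equal(g("p1", "SATISFICING_BIAS")$n_cases, 3)
  expect_equal(g("p1", "SATISFICING_BIAS")$n_possible, 6)
  expect_equal(g("p1", "SATISFICING_BIAS")$percent, 50.0)
  # p1 availability: 1 completed opportunity, flagged -> 100%
  expect_equal(g("p1", "AVAILABILITY_BIAS")$n_cases, 1)
  expect_equal(g("p1", "AVAILABILITY_BIAS")$n_possible, 1)
  # p1 gambler: c06 deviates (D after B, B) and is incorrect -> flagged
  expect_equal(g("p1", "GAMBLERS_BIAS")$n_cases, 1)
  expect_equal(g("p1", "GAMBLERS_BIAS")$percent, 100.0)

  # p2: c02 not completed, so the c07 opportunity loses its denominator
  # (predecessor exposure requires completing both preceding cases)
  expect_equal(g("p2", "AVAILABILITY_BIAS")$n_possible, 0)
  expect_true(is.na(g("p2", "AVAILABILITY_BIAS")$percent))
  expect_equal(g("p2", "AVAILABILITY_BIAS")$n_cases, 0)
  expect_equal(g("p2", "SATISFICING_BIAS")$n_possible, 5)

  # p3 never saw the X arm: availability denominator 0, gambler 1 with no
  # flag (answers B, D differ, so no two identical predecessors)
  expect_equal(g("p3", "AVAILABILITY_BIAS")$n_possible, 0)
  expect_equal(g("p3", "GAMBLERS_BIAS")$n_possible, 1)
  expect_equal(g("p3", "GAMBLERS_BIAS")$n_cases, 0)
  expect_equal(g("p3", "GAMBLERS_BIAS")$percent, 0.0)

  # column-sum invariant
  expect_true(all(fr$n_cases <= fr$n_possible))
})

test_that("a saturated configuration reports 100% for its label", {
  ex <- dxbias_example("study")
  plan <- build_default_plan(ex$cases, seed = 0)
  th <- list(satisficing = 1, availability = 0, gamblers = 0,
             confirmation = 0, anchor_bias = 0,
             representativeness_bias = 0)
  coh <- simulate_cohort(list(agent_profile(level = 3, p_dx = 1,
                                            theta = th)),
                         plan, ex$cases, ex$kb, seed = 13)
  rep <- detect_all(coh$sessions, ex$kb, plan, ex$cases)
  fr <- frequency_table(rep)
  # satisficing is injected on every non-opportunity case; with correct
  # answers elsewhere the flagged share of all completed cases is 24/40
  sat <- fr[fr$label == "SATISFICING_BIAS", ]
  expect_equal(sat$n_cases, 24)
  expect_equal(sat$percent, 60.0)
  expect_equal(fr$n_cases[fr$label == "AVAILABILITY_BIAS"], 0)
})

test_that("summaries use the median and RMS deviation about it", {
  fr <- data.frame(participant = paste0("p", 1:5), level = c(1, 1, 2, 2, 2),
                   label = "SATISFICING_BIAS", n_cases = 1:5,
                   n_possible = 10, percent = c(10, 20, 30, 40, 50))
  s <- summarize_frequencies(fr, by = "all")
  expect_equal(s$median, 30)
  expect_equal(s$sd_from_median, sqrt(mean((c(10, 20, 30, 40, 50) - 30)^2)))
  s2 <- summarize_frequencies(fr, by = "level")
  expect_equal(s2$median[s2$group == "1"], 15)
  expect_equal(s2$median[s2$group == "2"], 40)
})

test_that("error-bias association counts match a flat recount", {
  fx <- fixture_report()
  assoc <- error_bias_association(fx$rep)
  tab <- assoc$case_table
  # independent recount over the joined table
  expect_equal(assoc$pct_error_with_bias,
               round(100 * sum(tab$error & tab$any_bias) / sum(tab$error),
                     1))
  expect_equal(assoc$pct_correct_with_heuristic,
               round(100 * sum(!tab$error & tab$any_heuristic) /
                       sum(!tab$error), 1))
  expect_equal(assoc$n_completed, 14)
  # hand count: error cases are p1 c01,c02,c07,c06 and p2 c07, p3 c05;
  # of those, c01/c02/c06 (satisficing), c07 p1 (availability) carry bias
  expect_equal(sum(tab$error), 6)
  expect_equal(sum(tab$error & tab$any_bias), 4)
  expect_equal(assoc$pct_error_with_bias, round(100 * 4 / 6, 1))
})

test_that("a null cohort yields no bias-associated errors", {
  ex <- dxbias_example("study")
  plan <- build_default_plan(ex$cases, seed = 0)
  th <- list(satisficing = 0, availability = 0, gamblers = 0,
             confirmation = 0, anchor_bias = 0,
             representativeness_bias = 0)
  coh <- simulate_cohort(list(agent_profile(level = 1, p_find = 1, p_dx = 1,
                                            theta = th)),
                         plan, ex$cases, ex$kb, seed = 14)
  rep <- detect_all(coh$sessions, ex$kb, plan, ex$cases)
  assoc <- error_bias_association(rep)
  expect_equal(sum(assoc$case_table$error & assoc$case_table$any_bias), 0)
  expect_true(is.na(assoc$pct_error_with_bias))   # no error cases at all
})

test_that("group comparisons behave at the no-effect and separation poles", {
  fr <- data.frame(participant = paste0("p", 1:9),
                   level = rep(1:3, each = 3),
                   label = "SATISFICING_BIAS", n_cases = 0, n_possible = 10,
                   percent = rep(c(10, 20, 30), 3))
  cg <- compare_groups(fr)
  expect_lt(cg$kruskal$H, 0.5)
  expect_gt(cg$kruskal$p, 0.9)

  fr2 <- fr
  fr2$percent <- c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  cg2 <- compare_groups(fr2)
  pw <- cg2$pairwise
  expect_equal(pw$U[pw$group1 == "1" & pw$group2 == "2"], 0)
  expect_true(all(abs(pw$z) > 1.9))
  expect_error(compare_groups(fr[fr$level == 1, ]), "two non-empty groups")
})

test_that("the Kruskal-Wallis H matches an exhaustive permutation oracle", {
  fr <- data.frame(participant = paste0("p", 1:6),
                   level = rep(1:3, each = 2),
                   label = "L", n_cases = 0, n_possible = 1,
                   percent = c(1, 2, 3, 4, 5, 6))
  H_obs <- compare_groups(fr, label = "L")$kruskal$H
  # oracle: H from the rank formula for every assignment of 6 values into
  # three groups of two; the observed (fully separated) split attains the
  # maximum, and the statistic itself matches the formula
  perms <- combn(6, 2, simplify = FALSE)
  Hs <- c()
  for (g1 in perms) {
    rest <- setdiff(1:6, g1)
    for (g2 in combn(rest, 2, simplify = FALSE)) {
      g3 <- setdiff(rest, g2)
      r <- rank(1:6)
      rbar <- c(mean(r[g1]), mean(r[g2]), mean(r[g3]))
      H <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
      Hs <- c(Hs, H)
    }
  }
  expect_length(Hs, 90)
  expect_equal(H_obs, max(Hs))
  # observed assignment is groups (1,2),(3,4),(5,6)
  r <- rank(1:6)
  H_direct <- 12 / (6 * 7) * sum(2 * (c(mean(r[1:2]), mean(r[3:4]),
                                        mean(r[5:6])) - 3.5)^2)
  expect_equal(H_obs, H_direct)
})

test_that("summary CSV joins frequencies with mean confidence scores", {
  ex <- dxbias_example("study")
  plan <- build_default_plan(ex$cases, seed = 0)
  coh <- simulate_cohort(list(agent_profile(level = 1)), plan, ex$cases,
                         ex$kb, seed = 15)
  rep <- detect_all(coh$sessions, ex$kb, plan, ex$cases)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_summary_csv(rep, path)
  expect_true(file.exists(path))
  expect_true("mean_bias_score" %in% names(out))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 8)   # one row per label for one participant
  expect_true(all(back$n_cases <= back$n_possible))
})
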