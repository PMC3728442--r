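test_that("anchoring distinguishes heuristic, bias, and no episode", {
  kb <- toy_kb()
  # hypothesis, supporting finding, same diagnosis: appropriate nonadjustment
  ecs <- mk_evaluated(list(toy_bp = ev_stream(
    "H:bullous pemphigoid", "F:blister", "D:bullous pemphigoid", "CLOSE")))
  res <- detect_anchoring(ecs$toy_bp, kb)
  expect_equal(res$labels, "ANCHOR_HEURISTIC")

  # findings precede the hypothesis: no anchoring episode at all
  ecs <- mk_evaluated(list(toy_bp = ev_stream(
    "F:blister", "H:bullous pemphigoid", "D:bullous pemphigoid", "CLOSE")))
  expect_length(detect_anchoring(ecs$toy_bp, kb)$labels, 0)

  # finding does not support the kept diagnosis, never adjusted: bias
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "H:acne conglobata", "F:granuloma", "D:acne conglobata", "CLOSE")))
  expect_equal(detect_anchoring(ecs$toy_sar, kb)$labels, "ANCHOR_BIAS")

  # same, but a later diagnosis consistent with the findings: adjusted
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "H:acne conglobata", "F:granuloma", "D:acne conglobata",
    "D:sarcoidosis", "CLOSE")))
  res <- detect_anchoring(ecs$toy_sar, kb)
  expect_false("ANCHOR_BIAS" %in% res$labels)
  expect_true("ANCHOR_HEURISTIC" %in% res$labels)  # adjusted episode (H,D2)
})

test_that("anchoring adjustment also counts a diagnosis differing from the hypothesis", {
  kb <- toy_kb()
  # sufficient adjustment: diagnosis differs from the anchor but the
  # findings support it
  ecs <- mk_evaluated(list(toy_dh = ev_stream(
    "H:bullous pemphigoid", "F:neutrophils", "D:dermatitis herpetiformis",
    "CLOSE")))
  expect_equal(detect_anchoring(ecs$toy_dh, kb)$labels, "ANCHOR_HEURISTIC")
})

test_that("confirmation bias needs an incorrect diagnosis then a supporting finding", {
  kb <- toy_kb()
  # wrong diagnosis immediately shored up by a supporting finding
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "D:bullous pemphigoid", "F:blister", "H:sarcoidosis", "CLOSE")))
  expect_true(detect_confirmation(ecs$toy_sar, kb)$flag)

  # correct diagnosis: never confirmation bias
  ecs <- mk_evaluated(list(toy_bp = ev_stream(
    "D:bullous pemphigoid", "F:blister", "H:bullous pemphigoid", "CLOSE")))
  expect_false(detect_confirmation(ecs$toy_bp, kb)$flag)

  # an intervening action breaks immediacy under the default window
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "D:bullous pemphigoid", "H:sarcoidosis", "F:blister", "CLOSE")))
  expect_false(detect_confirmation(ecs$toy_sar, kb, window = "next")$flag)
  expect_true(detect_confirmation(ecs$toy_sar, kb,
                                  window = "any_later")$flag)

  # deletes and confidence marks are transparent to immediacy
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "D:bullous pemphigoid", "DEL:granuloma:finding", "F:blister",
    "H:sarcoidosis", "CLOSE")))
  expect_true(detect_confirmation(ecs$toy_sar, kb, window = "next")$flag)
})

test_that("satisficing requires premature closure on a deficient diagnosis", {
  # findings, hypothesis, incorrect diagnosis, immediate close: bias
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "F:granuloma", "H:acne conglobata", "D:acne conglobata", "CLOSE")))
  expect_true(detect_satisficing(ecs$toy_sar)$flag)

  # an intervening finding between hypothesis and diagnosis: no flag
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "H:acne conglobata", "F:granuloma", "D:acne conglobata", "CLOSE")))
  expect_false(detect_satisficing(ecs$toy_sar)$flag)

  # correct but incomplete differential still satisfices
  kb <- kb4(); cases <- cases4()
  s <- mk_sessions(list(c09 = ev_stream("H:C", "D:C", "CLOSE")))
  ec <- evaluate_session(s[[1]], kb, cases)$c09   # acceptable {C, D}
  expect_equal(ec$dx_verdict, "correct_incomplete")
  expect_true(detect_satisficing(ec)$flag)

  # a correct and complete diagnosis never satisfices
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "H:sarcoidosis", "D:sarcoidosis", "CLOSE")))
  expect_false(detect_satisficing(ecs$toy_sar)$flag)

  # an action between diagnosis and close blocks the flag
  ecs <- mk_evaluated(list(toy_sar = ev_stream(
    "H:acne conglobata", "D:acne conglobata", "H:sarcoidosis", "CLOSE")))
  expect_false(detect_satisficing(ecs$toy_sar)$flag)
})

test_that("representativeness needs a repeated taught pair, labelled per case", {
  kb <- toy_kb()
  # same taught pair in two cases, correct in both
  ecs <- mk_evaluated(list(
    toy_bp = ev_stream("F:blister", "D:bullous pemphigoid",
                       "H:bullous pemphigoid", "CLOSE"),
    toy_dh = ev_stream("F:blister", "D:bullous pemphigoid",
                       "H:dermatitis herpetiformis",
                       "D:dermatitis herpetiformis", "CLOSE")))
  res <- detect_representativeness(ecs, kb)
  expect_equal(res$toy_bp$labels, "REPR_HEURISTIC")   # correct there
  expect_equal(res$toy_dh$labels, "REPR_BIAS")        # incorrect there

  # a single occurrence is never labelled
  res1 <- detect_representativeness(ecs["toy_bp"], kb)
  expect_length(res1, 0)

  # non-taught pairs never qualify even when repeated
  ecs <- mk_evaluated(list(
    toy_bp = ev_stream("F:subepidermal split", "D:bullous pemphigoid",
                       "H:bullous pemphigoid", "CLOSE"),
    toy_dh = ev_stream("F:subepidermal split", "D:bullous pemphigoid",
                       "H:bullous pemphigoid", "CLOSE")))
  expect_length(detect_representativeness(ecs, kb), 0)
})

avail_fixture <- function(answer3) {
  kb <- kb4(); cases <- cases4()
  # c01, c02 acceptable {A}; c07 acceptable {C}: availability opportunity
  plan <- sequence_plan(list(X = c("c01", "c02", "c07")))
  streams <- list(
    c01 = ev_stream("H:A", "F:f1", "D:A", "CLOSE"),
    c02 = ev_stream("H:A", "F:f1", "D:A", "CLOSE"),
    c07 = ev_stream("H:A", "F:f3", paste0("D:", answer3), "CLOSE"))
  s <- mk_sessions(streams)
  list(evaluated = evaluate_session(s[[1]], kb, cases), plan = plan,
       cases = cases)
}

test_that("availability fires only on the predecessors' diagnosis", {
  fx <- avail_fixture("A")      # echoes the two preceding cases: bias
  expect_equal(names(detect_availability(fx$evaluated, fx$plan, fx$cases)),
               "c07")
  fx <- avail_fixture("B")      # wrong, but not the available diagnosis
  expect_length(detect_availability(fx$evaluated, fx$plan, fx$cases), 0)
  fx <- avail_fixture("C")      # correct answer
  expect_length(detect_availability(fx$evaluated, fx$plan, fx$cases), 0)
})

gamb_fixture <- function(a1, a2, a3) {
  kb <- kb4(); cases <- cases4()
  # c01, c02, c03 all acceptable {A}: gambler's-fallacy opportunity
  plan <- sequence_plan(list(X = c("c01", "c02", "c03")))
  streams <- list(
    c01 = ev_stream(paste0("H:", a1), paste0("D:", a1), "H:B", "CLOSE"),
    c02 = ev_stream(paste0("H:", a2), paste0("D:", a2), "H:B", "CLOSE"),
    c03 = ev_stream(paste0("H:", a3), paste0("D:", a3), "H:B", "CLOSE"))
  s <- mk_sessions(streams)
  list(evaluated = evaluate_session(s[[1]], kb, cases), plan = plan,
       cases = cases)
}

test_that("gambler's fallacy fires on deviation after two identical answers", {
  fx <- gamb_fixture("A", "A", "C")
  expect_equal(names(detect_gamblers(fx$evaluated, fx$plan, fx$cases)),
               "c03")
  fx <- gamb_fixture("A", "A", "A")   # no deviation
  expect_length(detect_gamblers(fx$evaluated, fx$plan, fx$cases), 0)
  # the first two answers may be identically wrong
  fx <- gamb_fixture("B", "B", "C")
  expect_equal(names(detect_gamblers(fx$evaluated, fx$plan, fx$cases)),
               "c03")
  fx <- gamb_fixture("B", "A", "C")   # predecessors disagree
  expect_length(detect_gamblers(fx$evaluated, fx$plan, fx$cases), 0)
})

test_that("the two worked single-case examples classify cleanly end to end", {
  kb <- toy_kb(); cases <- toy_cases()
  plan <- sequence_plan(list(SVD = "toy_bp", NDD = "toy_sar"))
  # second case: several findings, 'acne conglobata' as hypothesis and
  # (incorrect) final diagnosis, immediate close
  sessions <- mk_sessions(list(
    toy_bp = ev_stream("H:bullous pemphigoid", "F:blister",
                       "D:bullous pemphigoid", "CLOSE"),
    toy_sar = ev_stream("F:granuloma", "F:neutrophils", "H:acne conglobata",
                        "D:acne conglobata", "CLOSE")),
    participant = "demo")
  rep <- detect_all(sessions, kb, plan, cases)
  det <- rep$detections
  expect_equal(det$label[det$case_id == "toy_bp"], "ANCHOR_HEURISTIC")
  expect_equal(det$label[det$case_id == "toy_sar"], "SATISFICING_BIAS")
  expect_equal(nrow(det), 2)
})

test_that("an empty session set yields an empty report", {
  rep <- detect_all(structure(list(), class = "dxbias_sessions"),
                    toy_kb(), sequence_plan(list(X = "toy_bp")),
                    toy_cases())
  expect_equal(nrow(rep$detections), 0)
})

test_that("incomplete cases contribute no labels", {
  kb <- toy_kb()
  sessions <- mk_sessions(list(
    toy_sar = ev_stream("F:granuloma", "H:acne conglobata",
                        "D:acne conglobata")))   # never closed
  rep <- detect_all(sessions, kb, sequence_plan(list(X = "toy_sar")),
                    toy_cases())
  expect_equal(nrow(rep$detections), 0)
})

test_that("detectors agree with brute-force enumerators on random sessions", {
  kb <- kb4(); cases <- cases4()
  set.seed(101)
  for (i in 1:150) {
    fix <- random_session_fixture(kb, cases, n_cases = 6)
    rep <- detect_all(fix$sessions, kb, fix$plan, cases)
    evaluated <- rep$evaluated[[1]]
    expect_equal(canon(rep$detections),
                 canon(transform(oracle_report(evaluated, kb, fix$plan,
                                               cases),
                                 participant = "p1")),
                 info = paste("session", i))
  }
})

test_that("random sessions respect the opportunity bound and determinism", {
  kb <- kb4(); cases <- cases4()
  set.seed(202)
  for (i in 1:40) {
    fix <- random_session_fixture(kb, cases, n_cases = 8)
    r1 <- detect_all(fix$sessions, kb, fix$plan, cases)
    r2 <- detect_all(fix$sessions, kb, fix$plan, cases)
    expect_identical(r1$detections, r2$detections)
    n_av <- sum(r1$detections$label == "AVAILABILITY_BIAS")
    n_gb <- sum(r1$detections$label == "GAMBLERS_BIAS")
    expect_lte(n_av, length(enumerate_opportunities(fix$plan, cases,
                                                    "availability")))
    expect_lte(n_gb, length(enumerate_opportunities(fix$plan, cases,
                                                    "gamblers")))
    # label soundness: every evidence pointer refers to real events
    for (r in seq_len(nrow(r1$detections))) {
      evs <- strsplit(r1$detections$evidence[r], ",")[[1]]
      cid <- r1$detections$case_id[r]
      lab <- r1$detections$label[r]
      if (lab %in% c("AVAILABILITY_BIAS", "GAMBLERS_BIAS")) {
        expect_true(all(evs %in% unlist(fix$plan)))
      } else {
        expect_true(all(as.integer(evs) %in%
                          r1$evaluated[[1]][[cid]]$events$seq))
      }
    }
  }
})

test_that("sessions without a hypothesis-before-findings episode never anchor", {
  kb <- kb4(); cases <- cases4()
  set.seed(303)
  for (i in 1:30) {
    # streams built findings-first by construction
    n_f <- sample(1:4, 1)
    specs <- c(paste0("F:", sample(kb$findings, n_f, replace = TRUE)),
               paste0("H:", sample(kb$diagnoses, 1)),
               paste0("D:", sample(kb$diagnoses, 1)))
    s <- mk_sessions(list(c01 = ev_stream(specs, "CLOSE")))
    ec <- evaluate_session(s[[1]], kb, cases)$c01
    expect_length(detect_anchoring(ec, kb)$labels, 0)
  }
})
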