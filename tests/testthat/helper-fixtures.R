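# In-code fixtures and compact event-stream builders shared by the tests.

# Fig-2-style dermatitis micro-domain, mirroring the bundled toy files but
# built in code so unit tests do not depend on I/O.
toy_kb <- function() {
  knowledge_base(
    findings = c("blister", "subepidermal split", "eosinophils",
                 "neutrophils", "granuloma", "comedones"),
    diagnoses = c("bullous pemphigoid", "dermatitis herpetiformis",
                  "acne conglobata", "sarcoidosis"),
    relations = data.frame(
      finding = c("blister", "subepidermal split", "eosinophils",
                  "blister", "neutrophils", "granuloma", "comedones",
                  "eosinophils"),
      diagnosis = c("bullous pemphigoid", "bullous pemphigoid",
                    "bullous pemphigoid", "dermatitis herpetiformis",
                    "dermatitis herpetiformis", "sarcoidosis",
                    "acne conglobata", "dermatitis herpetiformis"),
      polarity = c(rep("support", 7), "refute"),
      stringsAsFactors = FALSE),
    taught_pairs = data.frame(
      finding = c("blister", "neutrophils", "granuloma", "comedones"),
      diagnosis = c("bullous pemphigoid", "dermatitis herpetiformis",
                    "sarcoidosis", "acne conglobata"),
      stringsAsFactors = FALSE)
  )
}

toy_cases <- function() {
  case_definitions(list(
    list(case_id = "toy_bp", subdomain = "SVD",
         acceptable_dx = "bullous pemphigoid",
         true_findings = c("blister", "subepidermal split", "eosinophils")),
    list(case_id = "toy_dh", subdomain = "SVD",
         acceptable_dx = "dermatitis herpetiformis",
         true_findings = c("blister", "neutrophils")),
    list(case_id = "toy_sar", subdomain = "NDD",
         acceptable_dx = "sarcoidosis", true_findings = "granuloma"),
    list(case_id = "toy_acne", subdomain = "NDD",
         acceptable_dx = "acne conglobata", true_findings = "comedones")
  ))
}

# Small abstract domain for property tests: 4 diagnoses, 6 findings.
kb4 <- function() {
  rel <- expand.grid(finding = paste0("f", 1:6),
                     diagnosis = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
  # fixed, irregular support structure
  keep <- c(1, 2, 8, 9, 10, 15, 16, 21, 22, 23)
  rel <- rel[keep, ]
  rel$polarity <- "support"
  tp <- rel[c(1, 3, 6, 8), c("finding", "diagnosis")]
  knowledge_base(paste0("f", 1:6), c("A", "B", "C", "D"), rel, tp)
}

# Case library over kb4 with repeated acceptable sets so random plans
# contain availability and gambler's-fallacy opportunities.
cases4 <- function() {
  recs <- list()
  sets <- list("A", "A", "A", "B", "B", "B", "C", "D", c("C", "D"), "A")
  for (i in seq_along(sets)) {
    recs[[i]] <- list(case_id = sprintf("c%02d", i), subdomain = "X",
                      acceptable_dx = sets[[i]],
                      true_findings = paste0("f", c(i %% 6 + 1,
                                                    (i + 2) %% 6 + 1)))
  }
  case_definitions(recs)
}

# Compact event-stream notation:
#   "H:label"  ADD_HYPOTHESIS   "F:label"  ADD_FINDING
#   "D:label"  ADD_DIAGNOSIS    "DEL:label[:kind]" DELETE_ITEM
#   "L:finding:hypothesis[:polarity]"  ADD_LINK
#   "MC:item:mark[:kind]" MARK_CONFIDENCE        "CLOSE"  CLOSE_CASE
ev_stream <- function(...) {
  specs <- c(...)
  rows <- lapply(seq_along(specs), function(i) {
    p <- strsplit(specs[i], ":", fixed = TRUE)[[1]]
    switch(p[1],
      H = new_event_df(i, "ADD_HYPOTHESIS", label = p[2]),
      F = new_event_df(i, "ADD_FINDING", label = p[2]),
      D = new_event_df(i, "ADD_DIAGNOSIS", label = p[2]),
      DEL = new_event_df(i, "DELETE_ITEM", label = p[2],
                         item_kind = if (length(p) > 2) p[3]
                                     else NA_character_),
      L = new_event_df(i, "ADD_LINK", label = p[2], label2 = p[3],
                       polarity = if (length(p) > 3) p[4] else "support"),
      MC = new_event_df(i, "MARK_CONFIDENCE", label = p[2], mark = p[3],
                        item_kind = if (length(p) > 3) p[4]
                                    else NA_character_),
      CLOSE = new_event_df(i, "CLOSE_CASE"),
      stop("bad spec: ", specs[i])
    )
  })
  do.call(rbind, rows)
}

new_event_df <- function(seq, kind, label = NA_character_,
                         label2 = NA_character_, polarity = NA_character_,
                         mark = NA_character_, item_kind = NA_character_) {
  data.frame(seq = as.integer(seq), kind = kind, label = label,
             label2 = label2, polarity = polarity, mark = mark,
             item_kind = item_kind, t = NA_character_,
             stringsAsFactors = FALSE)
}

# Build a one-participant dxbias_sessions object from named event streams.
mk_sessions <- function(streams, participant = "p1", level = 1L) {
  df <- do.call(rbind, lapply(names(streams), function(cid) {
    ev <- streams[[cid]]
    ev$participant <- participant
    ev$level <- level
    ev$case <- cid
    ev
  }))
  dxbias:::sessions_from_events(df)
}

mk_evaluated <- function(streams, kb = toy_kb(), cases = toy_cases(),
                         participant = "p1") {
  s <- mk_sessions(streams, participant = participant)
  evaluate_session(s[[1]], kb, cases)
}

# Random valid case stream over kb/case vocabularies, <= max_events events.
random_case_stream <- function(kb, cd, max_events = 12) {
  kinds <- c("F", "H", "D", "DEL", "L")
  n_body <- sample(0:(max_events - 3), 1)
  specs <- character()
  for (i in seq_len(n_body)) {
    k <- sample(kinds, 1, prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
    specs <- c(specs, switch(k,
      F = paste0("F:", sample(kb$findings, 1)),
      H = paste0("H:", sample(kb$diagnoses, 1)),
      D = paste0("D:", sample(kb$diagnoses, 1)),
      DEL = paste0("DEL:", sample(c(kb$findings, kb$diagnoses), 1)),
      L = paste0("L:", sample(kb$findings, 1), ":",
                 sample(kb$diagnoses, 1))))
  }
  has <- function(pfx) any(startsWith(specs, pfx))
  if (!has("H:")) specs <- c(specs, paste0("H:", sample(kb$diagnoses, 1)))
  if (!has("D:")) specs <- c(specs, paste0("D:", sample(kb$diagnoses, 1)))
  # deleting every diagnosis would leave no final differential; re-add one
  ev <- ev_stream(specs, "CLOSE")
  live <- dxbias:::replay_live(ev[ev$kind != "CLOSE_CASE", , drop = FALSE])
  if (!length(live$diagnoses)) {
    specs <- c(specs, paste0("D:", sample(kb$diagnoses, 1)))
    ev <- ev_stream(specs, "CLOSE")
  }
  ev
}

# Random one-participant session over a random plan drawn from cases4().
random_session_fixture <- function(kb = kb4(), cases = cases4(),
                                   n_cases = 6, max_events = 12) {
  ids <- sample(cases$case_id, n_cases)
  plan <- sequence_plan(list(X = ids))
  streams <- list()
  for (cid in ids) {
    streams[[cid]] <- random_case_stream(kb, NULL, max_events)
  }
  list(sessions = mk_sessions(streams), plan = plan, kb = kb, cases = cases)
}
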