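# Independent brute-force oracles: plain index scans over the event
# streams, written separately from the package's detectors. All share the
# frozen rule definitions but none of the implementation.

o_support <- function(kb, f, d) {
  any(kb$relations$finding == f & kb$relations$diagnosis == d &
        kb$relations$polarity == "support")
}
o_supports_all <- function(kb, fs, d) {
  length(fs) > 0 && all(vapply(fs, o_support, TRUE, kb = kb, d = d))
}

# all (kind, label, seq) triples of diagnostic add actions, in order
o_adds <- function(ev) {
  ev[ev$kind %in% c("ADD_FINDING", "ADD_HYPOTHESIS", "ADD_DIAGNOSIS",
                    "ADD_LINK"), , drop = FALSE]
}

oracle_anchoring <- function(ec, kb) {
  ev <- ec$events
  n <- nrow(ev)
  labs <- character()
  for (h in seq_len(n)) {
    if (ev$kind[h] != "ADD_HYPOTHESIS") next
    fs <- c()
    for (j in seq_len(n)) {
      if (j > h && ev$kind[j] == "ADD_FINDING") fs <- c(fs, j)
    }
    if (!length(fs)) next
    ep_f <- unique(ev$label[fs])
    for (d in seq_len(n)) {
      if (ev$kind[d] != "ADD_DIAGNOSIS" || d <= min(fs)) next
      if (o_supports_all(kb, ep_f, ev$label[d])) {
        labs <- c(labs, "ANCHOR_HEURISTIC")
      } else {
        adjusted <- FALSE
        for (m in seq_len(n)) {
          if (m > d && ev$kind[m] %in% c("ADD_HYPOTHESIS", "ADD_DIAGNOSIS") &&
              o_supports_all(kb, ep_f, ev$label[m])) adjusted <- TRUE
        }
        if (!adjusted) labs <- c(labs, "ANCHOR_BIAS")
      }
    }
  }
  sort(unique(labs))
}

oracle_confirmation <- function(ec, kb, window = "next") {
  ev <- ec$events
  adds <- o_adds(ev)
  for (i in seq_len(nrow(adds))) {
    if (adds$kind[i] != "ADD_DIAGNOSIS") next
    if (adds$label[i] %in% ec$case_def$acceptable_dx) next
    js <- if (window == "next") {
      if (i < nrow(adds)) i + 1 else integer()
    } else {
      seq_len(nrow(adds))[-seq_len(i)]
    }
    for (j in js) {
      if (adds$kind[j] == "ADD_FINDING" &&
          o_support(kb, adds$label[j], adds$label[i])) return(TRUE)
    }
  }
  FALSE
}

oracle_satisficing <- function(ec) {
  if (!ec$completed) return(FALSE)
  if (!isTRUE(ec$dx_verdict %in% c("incorrect", "correct_incomplete"))) {
    return(FALSE)
  }
  adds <- o_adds(ec$events)
  kinds <- adds$kind
  f_pos <- which(kinds == "ADD_FINDING")
  h_pos <- which(kinds == "ADD_HYPOTHESIS")
  if (!length(h_pos)) return(FALSE)
  if (length(f_pos) && max(f_pos) > min(h_pos)) return(FALSE)
  for (h in h_pos) {
    for (d in which(kinds == "ADD_DIAGNOSIS")) {
      if (d <= h) next
      between_f <- any(f_pos > h & f_pos < d)
      after <- d < length(kinds)   # any diagnostic action after d
      if (!between_f && !after) return(TRUE)
    }
  }
  FALSE
}

# session-level: returns data.frame(case_id, label)
oracle_representativeness <- function(evaluated, kb) {
  occ <- data.frame(f = character(), d = character(), case_id = character(),
                    correct = logical(), stringsAsFactors = FALSE)
  for (ec in evaluated) {
    adds <- o_adds(ec$events)
    if (nrow(adds) < 2) next
    for (i in seq_len(nrow(adds) - 1)) {
      if (adds$kind[i] == "ADD_FINDING" &&
          adds$kind[i + 1] == "ADD_DIAGNOSIS") {
        f <- adds$label[i]; d <- adds$label[i + 1]
        if (any(kb$taught_pairs$finding == f &
                  kb$taught_pairs$diagnosis == d)) {
          occ <- rbind(occ, data.frame(
            f = f, d = d, case_id = ec$case_id,
            correct = d %in% ec$case_def$acceptable_dx,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  out <- data.frame(case_id = character(), label = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(occ)) return(out)
  key <- paste(occ$f, occ$d)
  for (i in seq_len(nrow(occ))) {
    if (sum(key == key[i]) >= 2) {
      out <- rbind(out, data.frame(
        case_id = occ$case_id[i],
        label = if (occ$correct[i]) "REPR_HEURISTIC" else "REPR_BIAS",
        stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# sequence oracles: sliding window directly over the plan
oracle_sequence_flags <- function(evaluated, plan, cases, kind) {
  flagged <- character()
  for (sd in names(plan)) {
    ids <- plan[[sd]]
    if (length(ids) < 3) next
    for (k in 3:length(ids)) {
      acc <- lapply(ids[(k - 2):k],
                    function(id) cases$acceptable_dx[[match(id,
                                                            cases$case_id)]])
      if (!setequal(acc[[1]], acc[[2]])) next
      is_opp <- if (kind == "availability") {
        length(intersect(acc[[1]], acc[[3]])) == 0
      } else {
        setequal(acc[[1]], acc[[3]])
      }
      if (!is_opp) next
      e1 <- evaluated[[ids[k - 2]]]; e2 <- evaluated[[ids[k - 1]]]
      e3 <- evaluated[[ids[k]]]
      if (is.null(e1) || is.null(e2) || is.null(e3)) next
      if (!e1$completed || !e2$completed || !e3$completed) next
      if (is.na(e3$dx_verdict) || e3$dx_verdict != "incorrect") next
      hit <- if (kind == "availability") {
        length(intersect(e3$final_dx, acc[[1]])) > 0
      } else {
        setequal(e1$final_dx, e2$final_dx) &&
          !setequal(e3$final_dx, e1$final_dx)
      }
      if (hit) flagged <- c(flagged, ids[k])
    }
  }
  unique(flagged)
}

# full-report oracle for one participant's evaluated session
oracle_report <- function(evaluated, kb, plan, cases) {
  out <- data.frame(case_id = character(), label = character(),
                    stringsAsFactors = FALSE)
  addrow <- function(cid, lab) {
    out <<- rbind(out, data.frame(case_id = cid, label = lab,
                                  stringsAsFactors = FALSE))
  }
  completed <- Filter(function(e) e$completed, evaluated)
  for (ec in completed) {
    for (lab in oracle_anchoring(ec, kb)) addrow(ec$case_id, lab)
    if (oracle_confirmation(ec, kb)) addrow(ec$case_id, "CONFIRMATION_BIAS")
    if (oracle_satisficing(ec)) addrow(ec$case_id, "SATISFICING_BIAS")
  }
  rp <- oracle_representativeness(completed, kb)
  for (i in seq_len(nrow(rp))) addrow(rp$case_id[i], rp$label[i])
  for (cid in oracle_sequence_flags(evaluated, plan, cases, "availability")) {
    addrow(cid, "AVAILABILITY_BIAS")
  }
  for (cid in oracle_sequence_flags(evaluated, plan, cases, "gamblers")) {
    addrow(cid, "GAMBLERS_BIAS")
  }
  unique(out)
}

# canonicalize a detections data.frame for comparison
canon <- function(df) {
  df <- unique(df[, c("case_id", "label")])
  df <- df[order(df$case_id, df$label), ]
  rownames(df) <- NULL
  df
}
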