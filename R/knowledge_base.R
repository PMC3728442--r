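#' Construct a diagnostic knowledge base
#'
#' A knowledge base holds the controlled vocabularies of histopathologic
#' findings and diagnoses for a domain, the support/refute relations between
#' them, and the set of finding--diagnosis pairs explicitly taught during the
#' study period (the "learned model" that the representativeness rule
#' consumes).
#'
#' @param findings character vector of finding labels.
#' @param diagnoses character vector of diagnosis labels.
#' @param relations data.frame with columns `finding`, `diagnosis`,
#'   `polarity` (`"support"` or `"refute"`).
#' @param taught_pairs data.frame with columns `finding`, `diagnosis`; must be
#'   a subset of the supporting relations.
#'
#' @return An object of class `dxbias_kb`.
#' @export
knowledge_base <- function(findings, diagnoses, relations = NULL,
                           taught_pairs = NULL) {
  findings  <- unique(trimws(as.character(findings)))
  diagnoses <- unique(trimws(as.character(diagnoses)))
  if (is.null(relations)) {
    relations <- data.frame(finding = character(), diagnosis = character(),
                            polarity = character(), stringsAsFactors = FALSE)
  }
  relations <- data.frame(
    finding   = trimws(as.character(relations$finding)),
    diagnosis = trimws(as.character(relations$diagnosis)),
    polarity  = trimws(as.character(relations$polarity)),
    stringsAsFactors = FALSE
  )
  if (is.null(taught_pairs)) {
    taught_pairs <- data.frame(finding = character(), diagnosis = character(),
                               stringsAsFactors = FALSE)
  }
  taught_pairs <- data.frame(
    finding   = trimws(as.character(taught_pairs$finding)),
    diagnosis = trimws(as.character(taught_pairs$diagnosis)),
    stringsAsFactors = FALSE
  )
  kb <- structure(
    list(findings = findings, diagnoses = diagnoses,
         relations = relations, taught_pairs = taught_pairs),
    class = "dxbias_kb"
  )
  validate_kb(kb)
}

validate_kb <- function(kb) {
  rel <- kb$relations
  bad_pol <- setdiff(unique(rel$polarity), c("support", "refute"))
  if (length(bad_pol)) {
    stop("knowledge base: unknown relation polarity: ",
         paste(bad_pol, collapse = ", "), call. = FALSE)
  }
  bad_f <- setdiff(rel$finding, kb$findings)
  if (length(bad_f)) {
    stop("knowledge base: relation references undeclared finding(s): ",
         paste(unique(bad_f), collapse = ", "), call. = FALSE)
  }
  bad_d <- setdiff(rel$diagnosis, kb$diagnoses)
  if (length(bad_d)) {
    stop("knowledge base: relation references undeclared diagnosis/es: ",
         paste(unique(bad_d), collapse = ", "), call. = FALSE)
  }
  key <- paste(rel$finding, rel$diagnosis, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    pol_by_key <- tapply(rel$polarity, key, function(p) length(unique(p)))
    conflict <- names(pol_by_key)[pol_by_key > 1]
    if (length(conflict)) {
      stop("knowledge base: conflicting polarity for pair(s): ",
           paste(gsub("\r", " -> ", conflict), collapse = "; "),
           call. = FALSE)
    }
  }
  tp  <- kb$taught_pairs
  sup <- rel[rel$polarity == "support", , drop = FALSE]
  sup_key <- paste(sup$finding, sup$diagnosis, sep = "\r")
  tp_key  <- paste(tp$finding, tp$diagnosis, sep = "\r")
  missing <- setdiff(tp_key, sup_key)
  if (length(missing)) {
    stop("knowledge base: taught pair(s) without a support relation: ",
         paste(gsub("\r", " -> ", missing), collapse = "; "), call. = FALSE)
  }
  kb
}

#' Load a knowledge base from a JSON or YAML file
#'
#' The file must carry keys `findings` (array), `diagnoses` (array),
#' `relations` (array of objects with `finding`, `diagnosis`, `polarity`)
#' and optionally `taught_pairs` (array of two-element `[finding, diagnosis]`
#' arrays or of objects with those keys).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [knowledge_base()] object.
#' @export
load_kb <- function(path) {
  raw <- read_structured(path)
  for (k in c("findings", "diagnoses")) {
    if (is.null(raw[[k]])) {
      stop("knowledge base file ", path, ": missing key '", k, "'",
           call. = FALSE)
    }
  }
  rel <- raw$relations
  if (!is.null(rel) && !is.data.frame(rel)) {
    rel <- do.call(rbind, lapply(rel, function(r) {
      if (is.null(r$finding) || is.null(r$diagnosis) || is.null(r$polarity)) {
        stop("knowledge base file ", path,
             ": relation record missing finding/diagnosis/polarity: ",
             paste(unlist(r), collapse = " "), call. = FALSE)
      }
      data.frame(finding = r$finding, diagnosis = r$diagnosis,
                 polarity = r$polarity, stringsAsFactors = FALSE)
    }))
  }
  tp <- raw$taught_pairs
  if (!is.null(tp) && !is.data.frame(tp)) {
    if (is.matrix(tp)) {
      tp <- data.frame(finding = tp[, 1], diagnosis = tp[, 2],
                       stringsAsFactors = FALSE)
    } else {
      tp <- do.call(rbind, lapply(tp, function(p) {
        p <- unlist(p, use.names = FALSE)
        if (length(p) != 2) {
          stop("knowledge base file ", path,
               ": taught pair is not a [finding, diagnosis] pair: ",
               paste(p, collapse = " "), call. = FALSE)
        }
        data.frame(finding = p[1], diagnosis = p[2], stringsAsFactors = FALSE)
      }))
    }
  }
  knowledge_base(raw$findings, raw$diagnoses, rel, tp)
}

#' Look up the polarity of a finding--diagnosis relation
#'
#' @param kb a [knowledge_base()] object.
#' @param finding a finding label.
#' @param dx a diagnosis label.
#' @return `"support"`, `"refute"`, or `"none"`.
#' @export
supports <- function(kb, finding, dx) {
  stopifnot(inherits(kb, "dxbias_kb"))
  finding <- trimws(finding)
  dx <- trimws(dx)
  if (!finding %in% kb$findings) {
    stop("unknown finding label: '", finding, "'", call. = FALSE)
  }
  if (!dx %in% kb$diagnoses) {
    stop("unknown diagnosis label: '", dx, "'", call. = FALSE)
  }
  hit <- kb$relations$finding == finding & kb$relations$diagnosis == dx
  if (!any(hit)) return("none")
  kb$relations$polarity[which(hit)[1]]
}

# TRUE iff dx has a support relation from every finding in `findings`
# (vacuously TRUE on an empty finding set is never used by callers).
supported_by_all <- function(kb, findings, dx) {
  if (!length(findings)) return(FALSE)
  sup <- kb$relations[kb$relations$polarity == "support" &
                        kb$relations$diagnosis == dx, "finding"]
  all(findings %in% sup)
}

is_taught_pair <- function(kb, finding, dx) {
  any(kb$taught_pairs$finding == finding & kb$taught_pairs$diagnosis == dx)
}

#' Load case definitions
#'
#' Reads per-case ground truth: the acceptable diagnosis set (any member
#' counts as a correct answer) and the findings truly present. Accepts JSON
#' (array of objects with `case_id`, `subdomain`, `acceptable_dx`,
#' `true_findings`) or CSV with the same columns, lists separated by `;`.
#'
#' @param path path to a `.json`, `.yaml`/`.yml`, or `.csv` file.
#' @param kb optional [knowledge_base()]; when supplied, labels are checked
#'   against its vocabularies.
#' @return A data.frame of class `dxbias_cases` with list-columns
#'   `acceptable_dx` and `true_findings`.
#' @export
load_cases <- function(path, kb = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) {
      list(case_id = df$case_id[i], subdomain = df$subdomain[i],
           acceptable_dx = strsplit(df$acceptable_dx[i], ";")[[1]],
           true_findings = if (is.na(df$true_findings[i]) ||
                               !nzchar(df$true_findings[i])) character()
                           else strsplit(df$true_findings[i], ";")[[1]])
    })
  } else {
    recs <- read_structured(path)
    if (is.data.frame(recs)) {
      recs <- lapply(seq_len(nrow(recs)), function(i) as.list(recs[i, ]))
    }
  }
  case_definitions(recs, kb = kb)
}

#' Build a case-definition table from a list of records
#'
#' @param records list of lists with fields `case_id`, `subdomain`,
#'   `acceptable_dx`, `true_findings`.
#' @inheritParams load_cases
#' @return A `dxbias_cases` data.frame.
#' @export
case_definitions <- function(records, kb = NULL) {
  df <- data.frame(
    case_id   = vapply(records, function(r) trimws(as.character(r$case_id)), ""),
    subdomain = vapply(records, function(r) trimws(as.character(r$subdomain)), ""),
    stringsAsFactors = FALSE
  )
  df$acceptable_dx <- lapply(records, function(r)
    unique(trimws(unlist(r$acceptable_dx, use.names = FALSE))))
  df$true_findings <- lapply(records, function(r)
    unique(trimws(unlist(r$true_findings, use.names = FALSE))))
  if (anyDuplicated(df$case_id)) {
    stop("case definitions: duplicate case_id(s): ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  empty <- lengths(df$acceptable_dx) == 0
  if (any(empty)) {
    stop("case definitions: empty acceptable_dx for case(s): ",
         paste(df$case_id[empty], collapse = ", "), call. = FALSE)
  }
  if (!is.null(kb)) {
    bad_d <- setdiff(unlist(df$acceptable_dx), kb$diagnoses)
    if (length(bad_d)) {
      stop("case definitions: acceptable_dx not in knowledge base: ",
           paste(bad_d, collapse = ", "), call. = FALSE)
    }
    bad_f <- setdiff(unlist(df$true_findings), kb$findings)
    if (length(bad_f)) {
      stop("case definitions: true_findings not in knowledge base: ",
           paste(bad_f, collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("dxbias_cases", "data.frame")
  df
}

case_def <- function(cases, case_id) {
  i <- match(case_id, cases$case_id)
  if (is.na(i)) stop("unknown case_id: '", case_id, "'", call. = FALSE)
  list(case_id = cases$case_id[i], subdomain = cases$subdomain[i],
       acceptable_dx = cases$acceptable_dx[[i]],
       true_findings = cases$true_findings[[i]])
}

#' Classify a final diagnosis set against a case's acceptable set
#'
#' The system accepts any member of the acceptable set as a correct
#' diagnosis. A final differential that misses acceptable members is correct
#' but incomplete; one with no acceptable member is incorrect.
#'
#' @param case a case-definition record (a row of [load_cases()] output, via
#'   its `case_id`, or a list with `acceptable_dx`).
#' @param final_dx non-empty character vector: the final differential.
#' @return `"correct_complete"`, `"correct_incomplete"`, or `"incorrect"`.
#' @export
classify_diagnosis <- function(case, final_dx) {
  acc <- if (is.list(case) && !is.null(case$acceptable_dx))
    case$acceptable_dx else as.character(case)
  acc <- unlist(acc, use.names = FALSE)
  final_dx <- unique(trimws(final_dx))
  if (!length(final_dx)) {
    stop("classify_diagnosis: empty final diagnosis set (case closed with ",
         "no recorded diagnosis)", call. = FALSE)
  }
  if (!length(intersect(final_dx, acc))) return("incorrect")
  if (all(acc %in% final_dx)) return("correct_complete")
  "correct_incomplete"
}

#' @export
print.dxbias_kb <- function(x, ...) {
  cat("<dxbias knowledge base>\n",
      "  findings:     ", length(x$findings), "\n",
      "  diagnoses:    ", length(x$diagnoses), "\n",
      "  relations:    ", nrow(x$relations),
      " (", sum(x$relations$polarity == "support"), " support, ",
      sum(x$relations$polarity == "refute"), " refute)\n",
      "  taught pairs: ", nrow(x$taught_pairs), "\n", sep = "")
  invisible(x)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  }
}
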