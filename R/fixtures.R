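#' Bundled example data
#'
#' Two fixture sets ship with the package, both synthetic:
#' `"toy"` — a six-finding, four-diagnosis dermatitis knowledge base with
#' four cases, sized for worked examples; and `"study"` — a synthetic
#' study-scale library of two 20-case sub-domains (subepidermal vesicular
#' and nodular/diffuse dermatitides) whose diagnosis-group multiplicities
#' admit the default sequence plan.
#'
#' @param which `"toy"` or `"study"`.
#' @return A list with elements `kb` (a [knowledge_base()]) and `cases`
#'   (a case-definition table).
#' @export
#' @examples
#' ex <- dxbias_example("toy")
#' supports(ex$kb, "blister", "bullous pemphigoid")
dxbias_example <- function(which = c("toy", "study")) {
  which <- match.arg(which)
  files <- switch(which,
    toy = c(kb = "kb_dermatitis_toy.json",
            cases = "cases_dermatitis_toy.json"),
    study = c(kb = "kb_study_synthetic.json",
              cases = "cases_study_synthetic.json"))
  kb <- load_kb(system.file("extdata", files["kb"], package = "dxbias",
                            mustWork = TRUE))
  cases <- load_cases(system.file("extdata", files["cases"],
                                  package = "dxbias", mustWork = TRUE),
                      kb = kb)
  list(kb = kb, cases = cases)
}
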