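# Lexical variants per finding (every variant contains the finding's own
# vocabulary so labels remain recoverable from text), plus assertion and
# negation sentence frames. The negation lexicon is fixed: "no", "without",
# "resolved".
.FINDING_TERMS <- list(
  cardiomegaly = c("cardiomegaly", "mild cardiomegaly"),
  emphysema = c("emphysema", "emphysematous change"),
  effusion = c("pleural effusion", "a small pleural effusion"),
  hernia = c("hiatal hernia", "hernia"),
  nodule = c("a pulmonary nodule", "a small nodule"),
  atelectasis = c("atelectasis", "basilar atelectasis"),
  pneumonia = c("pneumonia", "pneumonia in the right lower lobe",
                "pneumonia in the left lower lobe", "multifocal pneumonia"),
  edema = c("pulmonary edema", "mild pulmonary edema"),
  consolidation = c("focal consolidation", "airspace consolidation"))

.POS_FRAMES <- c("there is %s.", "%s is seen.", "findings are consistent with %s.",
                 "interval development of %s.")
.NEG_FRAMES <- c("no %s.", "no evidence of %s.", "without %s.",
                 "%s has resolved.")

#' Generate a templated free-text report for one study
#'
#' Emits English sentences asserting each positive finding (drawing one of
#' several lexical variants) and explicit negations for a random subset of
#' the negative findings; hernia-positive studies always contain the word
#' "hernia". A report never asserts a finding whose label is 0 without a
#' negation cue, so ground-truth labels remain recoverable from text.
#' Consumes the current R random-number stream.
#'
#' @param labels Named binary vector over [FINDINGS].
#' @param view,department Optional metadata flavoring the opening sentence.
#' @param negation_rate Probability each negative finding is explicitly
#'   negated.
#' @return A single report string (lowercase).
#' @export
generate_report <- function(labels, view = "frontal", department = "outpatient",
                            negation_rate = 0.4) {
  labels <- labels[FINDINGS]
  stopifnot(!anyNA(labels), all(labels %in% c(0, 1)))
  sent <- c(if (department %in% c("inpatient", "ed")) "portable chest radiograph."
            else if (view == "lateral") "lateral chest radiograph."
            else "pa chest radiograph.")
  pos <- names(labels)[labels == 1]
  neg <- names(labels)[labels == 0]
  for (f in pos) {
    term <- sample(.FINDING_TERMS[[f]], 1L)
    sent <- c(sent, sprintf(sample(.POS_FRAMES, 1L), term))
  }
  for (f in neg) {
    if (runif(1) < negation_rate) {
      term <- sample(.FINDING_TERMS[[f]], 1L)
      sent <- c(sent, sprintf(sample(.NEG_FRAMES, 1L), term))
    }
  }
  if (length(pos) == 0L)
    sent <- c(sent, "no acute cardiopulmonary abnormality.")
  paste(sent, collapse = " ")
}

#' Generate reports for every study in a set
#'
#' @param set A `study_set` (or its `meta` data frame).
#' @param seed Seed fixing the report randomness.
#' @param negation_rate Passed to [generate_report()].
#' @return Data frame with columns `study_id`, `text`.
#' @export
generate_reports <- function(set, seed = 1L, negation_rate = 0.4) {
  meta <- if (inherits(set, "study_set")) set$meta else set
  set.seed(seed)
  texts <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    lab <- as.numeric(meta[i, FINDINGS])
    names(lab) <- FINDINGS
    texts[i] <- generate_report(lab, meta$view[i], meta$department[i],
                                negation_rate)
  }
  data.frame(study_id = meta$study_id, text = texts, stringsAsFactors = FALSE)
}
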