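# Classification targets derived from ESM self reports: the binary PANAS
# category, the 5-class valence / arousal ratings, and their 1-3 vs 4-5
# binarisation.

#' PANAS positive and negative sums
#'
#' The positive sum adds the four positive-affect items (inspired, active,
#' determined, attentive; range 4-20); the negative sum adds the six
#' negative-affect items (upset, hostile, alert, ashamed, nervous, afraid;
#' range 6-30).
#'
#' @param esm A one-row data frame / list with the ten PANAS items, or a
#'   multi-row ESM data frame (vectorised).
#' @return A data frame with columns `positive` and `negative`.
#' @export
panas_scores <- function(esm) {
  esm <- as.data.frame(as.list(esm) [c(panas_positive_items, panas_negative_items)])
  pos <- rowSums(esm[panas_positive_items])
  neg <- rowSums(esm[panas_negative_items])
  data.frame(positive = as.integer(pos), negative = as.integer(neg))
}

#' Binary PANAS category
#'
#' Class 1 (positive affect) when the positive sum exceeds the negative sum,
#' class 0 when the negative sum is larger. The comparison rule is undefined
#' at equality; tied instances are excluded (returned as `NA`) rather than
#' force-assigned, so they can be counted and reported instead of biasing the
#' class balance.
#'
#' @param positive_sum,negative_sum Integer sums from [panas_scores()]
#'   (vectorised).
#' @return Integer vector of 0 / 1 / `NA` (tie, excluded).
#' @export
panas_class <- function(positive_sum, negative_sum) {
  ifelse(positive_sum > negative_sum, 1L,
         ifelse(negative_sum > positive_sum, 0L, NA_integer_))
}

#' 5-class label from a 1-5 rating
#'
#' Valence and arousal ratings map to classes by identity: class index equals
#' the raw score.
#'
#' @param score Integer vector in 1..5.
#' @return The same integers, validated.
#' @export
scale_class <- function(score) {
  s <- as.numeric(score)
  bad <- is.na(s) | s < 1 | s > 5 | s != floor(s)
  if (any(bad)) {
    stopf("rating out of range [1,5]: %s", paste(score[bad], collapse = ", "))
  }
  as.integer(s)
}

#' Binarise a 5-class rating
#'
#' Classes 1-3 become category 0, classes 4-5 become category 1 (the
#' low/high split used to compare 5-class results with binary baselines).
#'
#' @param class Integer vector in 1..5.
#' @return Integer vector of 0/1.
#' @export
binarize_scale <- function(class) {
  cls <- scale_class(class)
  as.integer(cls >= 4L)
}

#' Full label set for one or more ESM responses
#'
#' @param esm An ESM data frame (rows from [read_esm()]).
#' @return A data frame with columns `panas_pos`, `panas_neg`, `panas_class`
#'   (0/1/NA for ties), `valence_class`, `arousal_class`, `valence_binary`,
#'   `arousal_binary`.
#' @export
label_set <- function(esm) {
  esm <- as.data.frame(esm)
  sc <- panas_scores(esm)
  data.frame(
    panas_pos = sc$positive,
    panas_neg = sc$negative,
    panas_class = panas_class(sc$positive, sc$negative),
    valence_class = scale_class(esm$valence),
    arousal_class = scale_class(esm$arousal),
    valence_binary = binarize_scale(esm$valence),
    arousal_binary = binarize_scale(esm$arousal)
  )
}

#' Class counts and proportions
#'
#' Tabulates a label column the way dataset-description tables report it:
#' count per class plus the proportion rounded to a whole percent.
#'
#' @param labels Vector of class labels (integers or factor).
#' @param classes Optional vector fixing the class universe (and row order);
#'   defaults to the sorted observed classes. `NA` labels (e.g. excluded
#'   PANAS ties) are dropped and counted in the `n_excluded` attribute.
#' @return Data frame with columns `class`, `count`, `percent`; attributes
#'   `n` (labels tabulated) and `n_excluded`.
#' @export
class_distribution <- function(labels, classes = NULL) {
  n_excluded <- sum(is.na(labels))
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stopf("no non-missing labels to tabulate")
  if (is.null(classes)) classes <- sort(unique(labels))
  counts <- vapply(classes, function(k) sum(labels == k), integer(1))
  structure(
    data.frame(class = classes, count = counts,
               percent = round(100 * counts / length(labels))),
    n = length(labels), n_excluded = n_excluded
  )
}
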