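#' Frontal-view filtering stage
#'
#' Trains a small binary view classifier (frontal vs lateral) on a labeled
#' subset of the studies and filters the remaining, "unlabeled" studies to
#' those predicted frontal; labeled studies are kept when truly frontal.
#' If the input contains no lateral studies there is nothing to learn or
#' remove and the set is returned unchanged.
#'
#' @param set A `study_set`.
#' @param labeled_sizes Named sizes of the manually labeled subset used to
#'   train and evaluate the view classifier (defaults 200/100/102; capped
#'   at the available studies).
#' @param seed Seed for the labeled-subset draw and training.
#' @param channels,schedule Classifier capacity and training schedule. The
#'   default schedule starts at a smaller learning rate (0.003) than the
#'   finding models: at desk scale the broad, high-contrast silhouette
#'   features destabilize the standard 0.01 rate.
#' @return List with `set` (filtered `study_set`), `accuracy` (held-out
#'   view accuracy with Clopper-Pearson CI, or `NA` when filtering was
#'   skipped), `n_test`, and `model`.
#' @export
view_filter <- function(set, labeled_sizes = c(train = 200, tune = 100, test = 102),
                        seed = 1L, channels = c(4L, 8L),
                        schedule = NULL) {
  stopifnot(inherits(set, "study_set"))
  meta <- set$meta
  if (!any(meta$view == "lateral"))
    return(list(set = set, accuracy = NA, n_test = 0L, model = NULL))
  set.seed(seed)
  n <- nrow(meta)
  sizes <- pmin(labeled_sizes, floor(n * c(0.5, 0.25, 0.25)))
  lab_idx <- sample.int(n, sum(sizes))
  part <- rep(c("train", "tune", "test"), times = sizes)
  tr <- lab_idx[part == "train"]; tu <- lab_idx[part == "tune"]
  te <- lab_idx[part == "test"]
  if (length(unique(meta$view[tr])) < 2L || length(unique(meta$view[tu])) < 2L)
    stop("labeled view subset contains a single class")
  S <- dim(set$images)[1]
  spec <- classifier_spec("multiclass", 2L, input_size = S,
                          channels = channels,
                          class_names = c("frontal", "lateral"))
  if (is.null(schedule))
    schedule <- train_schedule(initial_lr = 0.003, seed = seed)
  model <- train_classifier(set$images[, , tr], meta$view[tr],
                            set$images[, , tu], meta$view[tu],
                            spec, schedule)
  pred_class <- function(idx) {
    p <- predict_proba(model, set$images[, , idx, drop = FALSE])
    colnames(p)[max.col(p, ties.method = "first")]
  }
  acc_n <- length(te)
  acc_x <- sum(pred_class(te) == meta$view[te])
  rest <- setdiff(seq_len(n), lab_idx)
  keep_rest <- rest[pred_class(rest) == "frontal"]
  keep_lab <- lab_idx[meta$view[lab_idx] == "frontal"]
  list(set = subset_study_set(set, sort(c(keep_lab, keep_rest))),
       accuracy = clopper_pearson(acc_x, acc_n),
       n_test = acc_n, model = model)
}
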