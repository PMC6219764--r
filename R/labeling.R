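#' Tokenize text into unigram and bigram features
#'
#' Lowercases, splits on non-alphanumeric boundaries, and returns all
#' unigrams plus adjacent-pair bigrams (space-joined).
#'
#' @param text A single string.
#' @return Character vector of n-grams (possibly empty).
#' @export
text_ngrams <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  n <- length(toks)
  if (n == 0L) return(character(0))
  grams <- toks
  if (n >= 2L)
    grams <- c(grams, paste(toks[-n], toks[-1]))
  grams
}

#' Bag-of-words n-gram count features
#'
#' Builds the sparse document-by-n-gram count matrix over a vocabulary of
#' 1- and 2-grams. If no vocabulary is supplied, it is built from the texts
#' themselves (sorted unique n-grams); at prediction time, out-of-vocabulary
#' n-grams are ignored.
#'
#' @param texts Character vector of documents.
#' @param vocabulary Optional fixed, ordered n-gram vocabulary.
#' @return A `dgCMatrix` of counts, `length(texts)` rows, one column per
#'   vocabulary entry (column names = vocabulary). Empty text gives a zero
#'   row.
#' @export
featurize <- function(texts, vocabulary = NULL) {
  grams <- lapply(texts, text_ngrams)
  if (is.null(vocabulary))
    vocabulary <- sort(unique(unlist(grams)))
  ij <- lapply(seq_along(grams), function(i) {
    j <- match(grams[[i]], vocabulary)
    j <- j[!is.na(j)]
    if (length(j) == 0L) return(NULL)
    tab <- table(j)
    cbind(i = i, j = as.integer(names(tab)), x = as.integer(tab))
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(texts), length(vocabulary)),
                                dimnames = list(NULL, vocabulary)))
  Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = ij[, "x"],
                       dims = c(length(texts), length(vocabulary)),
                       dimnames = list(NULL, vocabulary))
}

#' Fit the n-gram Lasso report labeler
#'
#' L1-penalized logistic regression on 1-/2-gram counts, with the penalty
#' chosen by cross-validated log-loss (deviance) over the training
#' documents. Deterministic given `seed` (which fixes the fold assignment).
#'
#' @param texts Character vector of training documents.
#' @param labels Binary outcome per document; both classes must be present.
#' @param lambda Optional penalty grid (default: the glmnet path).
#' @param nfolds Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param threshold Decision threshold for [predict.ngram_label_model()]
#'   with `type = "class"`.
#' @return An object of class `ngram_label_model`: vocabulary, coefficient
#'   vector (same order), intercept, selected `lambda`, `threshold`, and
#'   the number of nonzero coefficients.
#' @export
fit_label_model <- function(texts, labels, lambda = NULL, nfolds = 5L,
                            seed = 1L, threshold = 0.5) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; cannot fit the labeler")
  stopifnot(length(texts) == length(labels))
  vocabulary <- sort(unique(unlist(lapply(texts, text_ngrams))))
  if (length(vocabulary) < 2L)
    stop("fewer than two distinct n-grams in the corpus")
  X <- featurize(texts, vocabulary)
  if (length(unique(texts)) < 2L) {
    # no lexical variation: the only honest model is intercept-only
    return(structure(list(vocabulary = vocabulary,
                          coefficients = setNames(numeric(length(vocabulary)),
                                                  vocabulary),
                          intercept = stats::qlogis(mean(labels)),
                          lambda = NA_real_, threshold = threshold,
                          n_nonzero = 0L, cv_lambda = NULL),
                     class = "ngram_label_model"))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = length(labels)))
  cv <- glmnet::cv.glmnet(X, labels, family = "binomial", alpha = 1,
                          foldid = foldid, lambda = lambda,
                          type.measure = "deviance", standardize = TRUE)
  cf <- as.vector(stats::coef(cv, s = "lambda.min"))
  structure(list(vocabulary = vocabulary,
                 coefficients = setNames(cf[-1], vocabulary),
                 intercept = cf[1],
                 lambda = cv$lambda.min,
                 threshold = threshold,
                 n_nonzero = sum(cf[-1] != 0),
                 cv_lambda = data.frame(lambda = cv$lambda,
                                        cvm = cv$cvm, nzero = cv$nzero)),
            class = "ngram_label_model")
}

#' Predict report labels or probabilities
#'
#' @param object An `ngram_label_model`.
#' @param texts Character vector of documents; out-of-vocabulary n-grams
#'   are ignored.
#' @param type `"response"` for probabilities, `"class"` for 0/1 labels at
#'   the model threshold.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.ngram_label_model <- function(object, texts,
                                      type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- featurize(texts, object$vocabulary)
  p <- stats::plogis(object$intercept +
                       as.vector(X %*% object$coefficients))
  if (type == "response") p else as.integer(p >= object$threshold)
}

#' Held-out performance of a report labeler
#'
#' AUC plus sensitivity and specificity at the model's classification
#' threshold (default 50%).
#'
#' @param model An `ngram_label_model`.
#' @param texts,labels Held-out documents and binary labels.
#' @return List with `auc` (an [auc_estimate()]), `sensitivity`,
#'   `specificity`, `accuracy`, and `n`.
#' @export
evaluate_label_model <- function(model, texts, labels) {
  labels <- as.numeric(labels)
  p <- predict(model, texts)
  pred <- as.integer(p >= model$threshold)
  list(auc = auc_estimate(p, labels),
       sensitivity = mean(pred[labels == 1] == 1),
       specificity = mean(pred[labels == 0] == 0),
       accuracy = mean(pred == labels),
       n = length(labels))
}

#' Keyword rule for hernia labels
#'
#' Case-insensitive whole-token match: a report is hernia-positive when the
#' word "hernia" appears (as a token, not inside a longer word).
#'
#' @param texts Character vector.
#' @return Integer vector of 0/1 labels.
#' @export
apply_hernia_rule <- function(texts) {
  as.integer(grepl("\\bhernia\\b", tolower(texts), perl = TRUE))
}

#' Serialize / restore a report labeler as JSON
#'
#' @param model An `ngram_label_model`.
#' @param path File path.
#' @return `write_label_model` invisibly returns `path`;
#'   `read_label_model` returns the restored model.
#' @export
write_label_model <- function(model, path) {
  stopifnot(inherits(model, "ngram_label_model"))
  jsonlite::write_json(list(vocabulary = model$vocabulary,
                            coefficients = unname(model$coefficients),
                            intercept = model$intercept,
                            lambda = model$lambda,
                            threshold = model$threshold),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_model
#' @export
read_label_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(vocabulary = obj$vocabulary,
                 coefficients = setNames(obj$coefficients, obj$vocabulary),
                 intercept = obj$intercept, lambda = obj$lambda,
                 threshold = obj$threshold,
                 n_nonzero = sum(obj$coefficients != 0)),
            class = "ngram_label_model")
}

#' @exportS3Method base::print
print.ngram_label_model <- function(x, ...) {
  cat(sprintf("<ngram_label_model> %d n-grams, %d nonzero coefficients, lambda %.4g\n",
              length(x$vocabulary), x$n_nonzero, x$lambda))
  invisible(x)
}
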