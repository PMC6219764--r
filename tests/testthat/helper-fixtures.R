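# Shared in-code fixtures: tiny study sets and scored sets built at test
# time; nothing is read from disk.

tiny_config <- function(n_patients = 40, size = 32, seed = 1, ...) {
  generator_config(n_patients_per_site = n_patients, image_size = size,
                   seed = seed, ...)
}

# Brute-force AUC by enumerating every positive-negative pair (ties 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Leave-one-out jackknife variance of the paired AUC difference.
jackknife_delta_var <- function(scores_a, scores_b, labels) {
  n <- length(labels)
  d <- vapply(seq_len(n), function(i) {
    auc_estimate(scores_a[-i], labels[-i])$auc -
      auc_estimate(scores_b[-i], labels[-i])$auc
  }, 0)
  (n - 1) / n * sum((d - mean(d))^2)
}

# Closed-form AUC of a two-valued score: positives/negatives split between
# a high-scoring and a low-scoring group.
two_value_auc <- function(pos_hi, pos_lo, neg_hi, neg_lo) {
  (pos_hi * neg_lo + 0.5 * (pos_hi * neg_hi + pos_lo * neg_lo)) /
    ((pos_hi + pos_lo) * (neg_hi + neg_lo))
}
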