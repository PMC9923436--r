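# brute-force AUC oracle: mean over all positive x negative pairs with half
# credit for ties (Mann-Whitney with ties)
auc_rank_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  w <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(w)
}

# random non-degenerate 2x2 counts (each margin non-empty)
random_counts <- function() {
  repeat {
    cells <- as.integer(rmultinom(1, sample(20:400, 1), runif(4, 0.05, 1)))
    if ((cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0) {
      return(confusion_counts(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}

# random integer-score cohort with both classes present
random_cohort_scores <- function(n = 60, max_score = 7) {
  repeat {
    scores <- sample(0:max_score, n, replace = TRUE)
    labels <- runif(n) < plogis((scores - max_score / 2) * 0.7)
    if (any(labels) && !all(labels)) return(list(scores = scores, labels = labels))
  }
}
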