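# K-nearest-neighbour classification with the package's fixed tie rules:
# distance ties are broken by the smaller training-row index, and an even
# class vote classifies positive. Scores are the fraction of the k
# neighbours labelled positive.
#
# Neighbours are found by k passes of max.col over the negated distance
# matrix (ties.method = "first" picks the lowest training index on ties),
# which is much faster than per-row order() calls at these sizes.

knn_score <- function(train_x, train_y, test_x, k = 5L) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  k <- min(as.integer(k), nrow(train_x))
  d <- -euclidean_cross(test_x, train_x)
  m <- nrow(d)
  rows <- seq_len(m)
  pos <- as.integer(train_y == 1L)
  votes <- numeric(m)
  for (j in seq_len(k)) {
    nb <- max.col(d, ties.method = "first")
    votes <- votes + pos[nb]
    d[cbind(rows, nb)] <- -Inf
  }
  votes / k
}

knn_label <- function(score) as.integer(score >= 0.5)
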