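# Independent oracles and small generators shared across the suite. These
# deliberately avoid the package's vectorized code paths: cosine
# similarities are recomputed per pair, losses use explicit double loops,
# and the AUC oracle is the rank-form Mann-Whitney statistic.

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

all_dna_upto <- function(max_len, alphabet = c("A", "C", "G", "T")) {
  unlist(lapply(seq_len(max_len), function(L) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1L, paste, collapse = "")
  }), use.names = FALSE)
}

cos_pair <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Double-loop reference of the thresholded self-supervised loss.
naive_self_loss <- function(Z, M, tau) {
  m <- nrow(Z)
  total <- 0
  for (a in seq_len(m)) {
    P <- setdiff(which(!is.na(M[a, ]) & M[a, ] == 1L), a)
    N <- setdiff(which(!is.na(M[a, ]) & M[a, ] == 0L), a)
    if (length(P) == 0L) next
    coef <- (length(P) + length(N)) / ((m - 1) * length(P))
    acc <- 0
    for (p in P) {
      den <- 0
      for (q in c(P, N)) den <- den + exp(cos_pair(Z[a, ], Z[q, ]) / tau)
      acc <- acc - log(exp(cos_pair(Z[a, ], Z[p, ]) / tau) / den)
    }
    total <- total + coef * acc
  }
  total
}

# Double-loop reference of the supervised contrastive loss.
naive_sup_loss <- function(Z, labels, tau) {
  m <- nrow(Z)
  total <- 0
  for (a in seq_len(m)) {
    others <- setdiff(seq_len(m), a)
    P <- others[labels[others] == labels[a]]
    if (length(P) == 0L) next
    acc <- 0
    for (p in P) {
      den <- 0
      for (q in others) den <- den + exp(cos_pair(Z[a, ], Z[q, ]) / tau)
      acc <- acc - log(exp(cos_pair(Z[a, ], Z[p, ]) / tau) / den)
    }
    total <- total + acc / length(P)
  }
  total
}

# Standard NT-Xent: each view's single positive is its sibling, the
# denominator runs over all other views.
naive_ntxent <- function(Z, sibling, tau) {
  m <- nrow(Z)
  total <- 0
  for (a in seq_len(m)) {
    den <- 0
    for (q in setdiff(seq_len(m), a)) {
      den <- den + exp(cos_pair(Z[a, ], Z[q, ]) / tau)
    }
    total <- total - log(exp(cos_pair(Z[a, ], Z[sibling[a], ]) / tau) / den)
  }
  total
}

# Normalized Mann-Whitney U statistic (average ranks for ties).
auc_rank_oracle <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A random symmetric pair-label matrix with NA diagonal.
random_label_matrix <- function(m, p_neutral = 0.2) {
  lab <- matrix(sample(c(0L, 1L, NA_integer_), m * m, replace = TRUE,
                       prob = c((1 - p_neutral) / 2, (1 - p_neutral) / 2,
                                p_neutral)), m, m)
  lab[lower.tri(lab)] <- t(lab)[lower.tri(lab)]
  diag(lab) <- NA_integer_
  lab
}

make_views_tibble <- function(n, L = 30L, labels = NULL) {
  d <- tibble::tibble(
    id = sprintf("r%d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) random_dna(L), ""),
    label = if (is.null(labels)) rep(0L, n) else labels
  )
  make_batch_views(d)
}
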