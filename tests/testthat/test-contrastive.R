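test_that("self_label applies strict thresholds with a neutral band", {
  t <- sim_thresholds(0.8, 0.7)
  # L = 20: similarities 19/20 = 0.95, 15/20 = 0.75, 10/20 = 0.5
  x <- strrep("ACGT", 5)
  near <- apply_edit(x, edit_op("delete_to_null", pos = 0))
  expect_equal(self_label(x, near, t), "positive")
  mid <- paste0(substr(x, 1, 15), "NNNNN")
  expect_equal(self_label(x, mid, t), "neutral")
  far <- paste0(substr(x, 1, 10), strrep("N", 10))
  expect_equal(self_label(x, far, t), "negative")
  # boundary exactly at a threshold is neutral
  s16 <- paste0(substr(x, 1, 16), "NNNN")  # similarity 0.8
  expect_equal(self_label(x, s16, t), "neutral")
  s14 <- paste0(substr(x, 1, 14), "NNNNNN")  # similarity 0.7
  expect_equal(self_label(x, s14, t), "neutral")
})

test_that("threshold presets cover the no-neutral variants", {
  expect_equal(threshold_preset("default"), sim_thresholds(0.8, 0.7))
  expect_equal(threshold_preset("editCLR-0.7"), sim_thresholds(0.7, 0.7))
  expect_equal(threshold_preset("editCLR-0.8"), sim_thresholds(0.8, 0.8))
  expect_error(sim_thresholds(0.5, 0.8), ">=")
})

test_that("sup_label is positive iff origin labels agree", {
  expect_equal(sup_label(1L, 1L), "positive")
  expect_equal(sup_label(0L, 0L), "positive")
  expect_equal(sup_label(0L, 1L), "negative")
  expect_error(sup_label(2L, 1L), "0 or 1")
})

test_that("build_pair_labels is symmetric with the right positives per mode", {
  set.seed(20)
  views <- make_views_tibble(4, labels = c(1L, 1L, 0L, 1L))
  for (mode in c("editclr", "supclr", "simclr")) {
    M <- build_pair_labels(views, contrastive_config(mode = mode))
    expect_true(all(is.na(diag(M))))
    expect_identical(M[upper.tri(M)], t(M)[upper.tri(M)])
  }
  # simclr: exactly one positive per view, its sibling
  M <- build_pair_labels(views, contrastive_config(mode = "simclr"))
  for (a in 1:8) {
    expect_equal(sum(M[a, ] == 1L, na.rm = TRUE), 1L)
    sib <- a + ifelse(a %% 2 == 1, 1L, -1L)
    expect_equal(M[a, sib], 1L)
  }
  # supclr: same-origin-label views are positive, never neutral
  M <- build_pair_labels(views, contrastive_config(mode = "supclr"))
  expect_false(anyNA(M[upper.tri(M)]))
  same <- outer(views$origin_label, views$origin_label, `==`)
  expect_equal(M[upper.tri(M)], as.integer(same)[upper.tri(same)])
  # supclr with all labels equal: every off-diagonal pair positive
  views1 <- make_views_tibble(3, labels = c(1L, 1L, 1L))
  M1 <- build_pair_labels(views1, contrastive_config(mode = "supclr"))
  expect_true(all(M1[upper.tri(M1)] == 1L))
  # editclr: sibling views always positive (similarity > 0.9 > 0.8)
  M <- build_pair_labels(views, contrastive_config(mode = "editclr"))
  for (a in seq(1, 8, by = 2)) expect_equal(M[a, a + 1L], 1L)
})

test_that("cosine similarity handles identity, orthogonality and zero vectors", {
  v <- c(1, 2, 3)
  expect_equal(cosine_sim(v, v), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(0, 0), v[1:2]), 0)
  expect_equal(cosine_sim(v, -v), -1)
  expect_error(cosine_sim(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("self loss matches the double-loop reference on random batches", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    m <- 2L * n
    Z <- matrix(rnorm(m * 16), m)
    M <- random_label_matrix(m)
    tau <- sample(c(1.0, 0.1, 0.01), 1)
    expect_equal(self_contrastive_loss(Z, M, tau), naive_self_loss(Z, M, tau),
                 tolerance = 1e-10)
  }
})

test_that("sup loss matches the double-loop reference on random batches", {
  set.seed(34)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    m <- 2L * n
    Z <- matrix(rnorm(m * 16), m)
    labels <- sample(0:1, m, replace = TRUE)
    tau <- sample(c(1.0, 0.1, 0.01), 1)
    expect_equal(sup_contrastive_loss(Z, labels, tau),
                 naive_sup_loss(Z, labels, tau), tolerance = 1e-10)
  }
})

test_that("single-positive labeling reduces the self loss to NT-Xent", {
  set.seed(35)
  n <- 6L; m <- 2L * n
  Z <- matrix(rnorm(m * 8), m)
  sib <- ifelse(seq_len(m) %% 2 == 1, seq_len(m) + 1L, seq_len(m) - 1L)
  M <- matrix(0L, m, m)
  M[cbind(seq_len(m), sib)] <- 1L
  diag(M) <- NA_integer_
  for (tau in c(1.0, 0.1)) {
    expect_equal(self_contrastive_loss(Z, M, tau), naive_ntxent(Z, sib, tau),
                 tolerance = 1e-10)
  }
})

test_that("hand-computed degenerate cases are exact", {
  # n = 1: two mutual positives, no negatives -> each ratio is 1, loss 0
  Z <- matrix(rnorm(2 * 4), 2)
  M <- matrix(c(NA, 1L, 1L, NA), 2)
  expect_equal(self_contrastive_loss(Z, M, 0.5), 0, tolerance = 1e-12)
  # n = 2, all same class, identical embeddings: every ratio 1/3,
  # total = 4 log 3 (temperature cancels)
  Z4 <- matrix(rep(c(1, 2, 3), each = 4), 4)
  expect_equal(sup_contrastive_loss(Z4, rep(1L, 4), 0.07), 4 * log(3),
               tolerance = 1e-9)
})

test_that("losses are non-negative and permutation-invariant", {
  set.seed(36)
  for (rep in 1:10) {
    m <- 8L
    Z <- matrix(rnorm(m * 12), m)
    M <- random_label_matrix(m)
    labels <- sample(0:1, m, replace = TRUE)
    l1 <- self_contrastive_loss(Z, M, 0.2)
    l2 <- sup_contrastive_loss(Z, labels, 0.2)
    expect_gte(l1, 0); expect_gte(l2, 0)
    perm <- sample(m)
    expect_equal(self_contrastive_loss(Z[perm, ], M[perm, perm], 0.2), l1,
                 tolerance = 1e-10)
    expect_equal(sup_contrastive_loss(Z[perm, ], labels[perm], 0.2), l2,
                 tolerance = 1e-10)
  }
})

test_that("neutral pairs are excluded from numerator and denominator", {
  set.seed(37)
  m <- 6L
  Z <- matrix(rnorm(m * 5), m)
  M <- random_label_matrix(m, p_neutral = 0)
  base <- self_contrastive_loss(Z, M, 0.3)
  # adding a view that is neutral to everything leaves the loss unchanged
  Zbig <- rbind(Z, rnorm(5))
  Mbig <- rbind(cbind(M, NA_integer_), NA_integer_)
  # per-view scale (|P|+|N|)/(|A| |P|) changes because |A| grows by 1
  expect_equal(self_contrastive_loss(Zbig, Mbig, 0.3),
               naive_self_loss(Zbig, Mbig, 0.3), tolerance = 1e-10)
  # directly: zero out the neutral view's effect by comparing per-term sums
  scale_old <- (m - 1)
  scale_new <- m
  expect_equal(self_contrastive_loss(Zbig, Mbig, 0.3) * scale_new,
               base * scale_old, tolerance = 1e-9)
})

test_that("per-view contributions stay within the single-positive-pair scale", {
  set.seed(38)
  m <- 10L
  Z <- matrix(rnorm(m * 6), m)
  M <- random_label_matrix(m)
  tau <- 0.5
  # bound: each view term <= max single log-ratio magnitude over its pairs
  total <- self_contrastive_loss(Z, M, tau)
  # crude upper bound: (2/tau) per positive-pair log-ratio, m views
  expect_lte(total, m * (2 / tau + log(m)))
})

test_that("temperature must be positive", {
  Z <- matrix(rnorm(8), 4)
  M <- random_label_matrix(4)
  expect_error(self_contrastive_loss(Z, M, 0), "positive")
  expect_error(sup_contrastive_loss(Z, c(0L, 1L, 0L, 1L), -1), "positive")
  expect_error(contrastive_config(temperature = 0), "> 0")
})
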