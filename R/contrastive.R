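#' Similarity thresholds for self-supervised pair labeling
#'
#' A pair of augmented sequences is positive when its normalized edit
#' similarity exceeds `positive`, negative when it falls below
#' `negative`, and neutral otherwise (boundary values are neutral; both
#' inequalities are strict). The defaults (0.8, 0.7) come from the
#' threshold-selection statistics over similarity intervals; presets with
#' equal thresholds reproduce the no-neutral-pair variants.
#'
#' @param positive Positive threshold in `[0, 1]`.
#' @param negative Negative threshold in `[0, 1]`, `<= positive`.
#' @return A list of class `sim_thresholds`.
#' @export
sim_thresholds <- function(positive = 0.8, negative = 0.7) {
  stopifnot(positive >= 0, positive <= 1, negative >= 0, negative <= 1)
  if (positive < negative) abort("`positive` must be >= `negative`.")
  structure(list(positive = positive, negative = negative),
            class = "sim_thresholds")
}

#' @rdname sim_thresholds
#' @param name Preset name: `"default"` (0.8/0.7), `"editCLR-0.7"` (both
#'   0.7) or `"editCLR-0.8"` (both 0.8).
#' @export
threshold_preset <- function(name = c("default", "editCLR-0.7", "editCLR-0.8")) {
  switch(match.arg(name),
         "default" = sim_thresholds(0.8, 0.7),
         "editCLR-0.7" = sim_thresholds(0.7, 0.7),
         "editCLR-0.8" = sim_thresholds(0.8, 0.8))
}

#' Self-supervised pair label from sequence similarity
#'
#' @param x_a,x_b Equal-length DNA sequences (augmented views).
#' @param thresholds A [sim_thresholds()].
#' @return `"positive"`, `"negative"`, or `"neutral"`.
#' @export
self_label <- function(x_a, x_b, thresholds = sim_thresholds()) {
  sim <- sequence_similarity(x_a, x_b)
  label_from_similarity(sim, thresholds)
}

label_from_similarity <- function(sim, thresholds) {
  dplyr::case_when(
    sim > thresholds$positive ~ "positive",
    sim < thresholds$negative ~ "negative",
    TRUE ~ "neutral"
  )
}

#' Supervised pair label from record labels
#'
#' Positive iff the two origin labels agree; never neutral.
#'
#' @param y_a,y_b Binary labels in `{0, 1}`.
#' @return `"positive"` or `"negative"`.
#' @export
sup_label <- function(y_a, y_b) {
  if (!all(c(y_a, y_b) %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  if (y_a == y_b) "positive" else "negative"
}

#' Contrastive configuration
#'
#' @param mode Pair-labeling mode: `"editclr"` (similarity-thresholded
#'   labels over all view pairs, neutral pairs excluded from the loss),
#'   `"supclr"` (origin labels decide positives), or `"simclr"` (sibling
#'   views positive, all other pairs negative; similarity is never
#'   computed).
#' @param temperature Positive temperature `tau` scaling the cosine
#'   similarities inside the loss; default 0.1.
#' @param thresholds A [sim_thresholds()] (editclr mode only).
#' @return A list of class `contrastive_config`.
#' @export
contrastive_config <- function(mode = c("editclr", "supclr", "simclr"),
                               temperature = 0.1,
                               thresholds = sim_thresholds()) {
  mode <- match.arg(mode)
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be > 0.")
  }
  structure(list(mode = mode, temperature = temperature,
                 thresholds = thresholds), class = "contrastive_config")
}

#' Build the 2n x 2n pair-label matrix for a batch of views
#'
#' Returns a symmetric matrix over the augmented views with entries
#' `1` (positive), `0` (negative) or `NA` (neutral; editclr mode only).
#' The diagonal is `NA` and never read. In editclr mode the normalized
#' edit similarity is computed for all `C(2n, 2)` view pairs (the
#' augmented sequences themselves, not their origins); supclr compares
#' origin labels; simclr marks exactly the sibling view positive.
#'
#' @param views A view tibble from [make_batch_views()].
#' @param config A [contrastive_config()].
#' @return An integer matrix of class `pair_label_matrix` with attribute
#'   `mode`.
#' @export
build_pair_labels <- function(views, config = contrastive_config()) {
  stopifnot(is.data.frame(views),
            all(c("origin_index", "origin_label", "sequence") %in% names(views)))
  m <- nrow(views)
  lab <- switch(config$mode,
    editclr = {
      S <- similarity_matrix(views$sequence)
      out <- matrix(NA_integer_, m, m)
      out[S > config$thresholds$positive] <- 1L
      out[S < config$thresholds$negative] <- 0L
      out
    },
    supclr = {
      same <- outer(views$origin_label, views$origin_label, `==`)
      matrix(as.integer(same), m, m)
    },
    simclr = {
      sib <- outer(views$origin_index, views$origin_index, `==`)
      matrix(as.integer(sib), m, m)
    }
  )
  diag(lab) <- NA_integer_
  structure(lab, class = "pair_label_matrix", mode_label = config$mode)
}

#' Cosine similarity of two embeddings
#'
#' `dot(a, b) / (||a|| ||b||)`; defined as 0 when either norm is 0 (a
#' global-max-pooled embedding can be all zero under rectification).
#'
#' @param z_a,z_b Numeric vectors of equal dimension.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) abort("Embedding dimensions must match.")
  na <- sqrt(sum(z_a^2)); nb <- sqrt(sum(z_b^2))
  if (na == 0 || nb == 0) return(0)
  sum(z_a * z_b) / (na * nb)
}

# Row-normalize and form the full cosine-similarity matrix; zero rows map
# to zero similarity.
cosine_sim_matrix <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  U <- Z / ifelse(nrm > 0, nrm, 1)
  U[nrm == 0, ] <- 0
  U %*% t(U)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    abort("`temperature` must be a positive scalar.")
  }
}

#' Self-supervised contrastive loss with neutral-pair exclusion
#'
#' NT-Xent-style loss over `2n` embeddings where each view's positive and
#' negative sets come from a [build_pair_labels()] matrix. For view `a`
#' with positives `P`, negatives `N` and `|A| = 2n - 1` other views, the
#' per-view term is
#' `-(|P|+|N|)/(|A| |P|) * sum_{p in P} log( exp(cos(z_a,z_p)/tau) /
#' sum_{q in P u N} exp(cos(z_a,z_q)/tau) )`.
#' Neutral pairs appear in neither numerator nor denominator; the leading
#' scale keeps every view's contribution within the scale of a
#' single-positive-pair loss. Views with no positives contribute 0.
#' Computed with log-sum-exp stabilization; always non-negative.
#'
#' @param Z A `2n x d` embedding matrix (rows are views).
#' @param M A `pair_label_matrix` (editclr or simclr labeling).
#' @param temperature Positive temperature.
#' @return Non-negative scalar loss.
#' @export
self_contrastive_loss <- function(Z, M, temperature = 0.1) {
  check_tau(temperature)
  self_loss_grad(Z, M, temperature, want_grad = FALSE)$loss
}

#' Supervised contrastive loss
#'
#' For view `a` with positives `P` (other views sharing `a`'s origin
#' label) the per-view term is
#' `-(1/|P|) sum_{p in P} log( exp(cos(z_a,z_p)/tau) /
#' sum_{q != a} exp(cos(z_a,z_q)/tau) )` — the denominator runs over all
#' other views. Views with no positives contribute 0.
#'
#' @param Z A `2n x d` embedding matrix.
#' @param origin_labels Per-view binary labels (length `2n`).
#' @param temperature Positive temperature.
#' @return Non-negative scalar loss.
#' @export
sup_contrastive_loss <- function(Z, origin_labels, temperature = 0.1) {
  check_tau(temperature)
  sup_loss_grad(Z, origin_labels, temperature, want_grad = FALSE)$loss
}

# Shared machinery: loss and (optionally) gradient w.r.t. Z for the
# thresholded self-supervised loss. P/N sets are read off the label
# matrix; D = P u N is the denominator set.
self_loss_grad <- function(Z, M, temperature, want_grad = TRUE) {
  m <- nrow(Z)
  S <- cosine_sim_matrix(Z)
  G <- if (want_grad) matrix(0, m, m) else NULL
  loss <- 0
  for (a in seq_len(m)) {
    P <- which(M[a, ] == 1L); P <- P[P != a]
    N <- which(M[a, ] == 0L); N <- N[N != a]
    nP <- length(P); nN <- length(N)
    if (nP == 0L) next
    coef <- (nP + nN) / ((m - 1) * nP)
    D <- c(P, N)
    logits <- S[a, D] / temperature
    mx <- max(logits)
    lse <- mx + log(sum(exp(logits - mx)))
    loss <- loss + coef * sum(lse - S[a, P] / temperature)
    if (want_grad) {
      w <- exp(logits - lse)  # softmax over D
      G[a, D] <- G[a, D] + coef / temperature * nP * w
      G[a, P] <- G[a, P] - coef / temperature
    }
  }
  grad <- if (want_grad) cosine_backward(Z, G) else NULL
  list(loss = loss, grad = grad)
}

sup_loss_grad <- function(Z, origin_labels, temperature, want_grad = TRUE) {
  m <- nrow(Z)
  if (length(origin_labels) != m) abort("One label per view is required.")
  S <- cosine_sim_matrix(Z)
  G <- if (want_grad) matrix(0, m, m) else NULL
  loss <- 0
  for (a in seq_len(m)) {
    others <- setdiff(seq_len(m), a)
    P <- others[origin_labels[others] == origin_labels[a]]
    nP <- length(P)
    if (nP == 0L) next
    logits <- S[a, others] / temperature
    mx <- max(logits)
    lse <- mx + log(sum(exp(logits - mx)))
    loss <- loss + (1 / nP) * sum(lse - S[a, P] / temperature)
    if (want_grad) {
      w <- exp(logits - lse)
      G[a, others] <- G[a, others] + w / temperature
      G[a, P] <- G[a, P] - 1 / (nP * temperature)
    }
  }
  grad <- if (want_grad) cosine_backward(Z, G) else NULL
  list(loss = loss, grad = grad)
}

# Backpropagate dL/dS (S = U U^T on row-normalized U) to dL/dZ.
cosine_backward <- function(Z, G) {
  nrm <- sqrt(rowSums(Z^2))
  safe <- ifelse(nrm > 0, nrm, 1)
  U <- Z / safe
  U[nrm == 0, ] <- 0
  dU <- (G + t(G)) %*% U
  proj <- rowSums(dU * U)
  dZ <- (dU - U * proj) / safe
  dZ[nrm == 0, ] <- 0
  dZ
}
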