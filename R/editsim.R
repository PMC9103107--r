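#' Character matching score
#'
#' Literal equality over `{A, C, G, T, N}`: 1 for a match, 0 otherwise.
#' By default `N == N` scores 1 (literal equality); set
#' `n_matches_n = FALSE` to treat the null token as matching nothing.
#'
#' @param a,b Single DNA characters.
#' @param n_matches_n Should two null tokens count as a match? Default `TRUE`.
#' @return Integer 0 or 1.
#' @export
char_match <- function(a, b, n_matches_n = TRUE) {
  for (ch in c(a, b)) {
    if (!is.character(ch) || length(ch) != 1L || !ch %in% DNA_ALPHABET) {
      abort("Characters must be single letters in {A,C,G,T,N}.")
    }
  }
  if (!n_matches_n && a == "N" && b == "N") return(0L)
  as.integer(a == b)
}

#' Needleman-Wunsch score (match = 1, mismatch = indel = 0)
#'
#' Global-alignment prefix score `F[p][q] = max(F[p-1][q-1] + match,
#' F[p-1][q], F[p][q-1])` with a zero boundary. Under this
#' parameterization the score equals the length of the longest common
#' subsequence: it reaches the sequence length only for identical
#' sequences and 0 only when the two sequences share no token types.
#'
#' @param x_i,x_j DNA sequence strings (lengths may differ).
#' @return Integer alignment score.
#' @examples
#' nw_score("ACGT", "ACGT") # 4
#' nw_score("AAAA", "CCCC") # 0
#' @export
nw_score <- function(x_i, x_j) {
  x_i <- parse_sequence(x_i)
  x_j <- parse_sequence(x_j)
  .nw_score_cpp(x_i, x_j)[1]
}

#' Normalized edit similarity of two equal-length sequences
#'
#' The Needleman-Wunsch score divided by the common length `L`, a
#' symmetric similarity in `[0, 1]` that is 1 exactly for identical
#' sequences and 0 for sequences with disjoint token sets.
#'
#' @inheritParams nw_score
#' @return Similarity in `[0, 1]`.
#' @examples
#' sequence_similarity("ACGT", "TGCA") # 0.25
#' @export
sequence_similarity <- function(x_i, x_j) {
  x_i <- parse_sequence(x_i)
  x_j <- parse_sequence(x_j)
  L <- nchar(x_i)
  if (nchar(x_j) != L) {
    abort("Similarity is defined for equal-length sequences only.")
  }
  .nw_score_cpp(x_i, x_j)[1] / L
}

# Vectorized similarity for aligned vectors of equal-length sequences.
sequence_similarity_many <- function(x, y) {
  L <- nchar(x)
  if (any(nchar(y) != L)) abort("Pairwise similarity needs equal lengths.")
  .nw_score_cpp(x, y) / L
}

#' Full pairwise similarity matrix
#'
#' Computes the normalized edit similarity for every unordered pair in a
#' vector of equal-length sequences (the O(n^2 L^2) kernel of the
#' self-supervised pair labeling).
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @return A symmetric `n x n` numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(seqs) {
  seqs <- validate_sequences(seqs)
  .nw_sim_matrix_cpp(seqs)
}

#' Brute-force longest-common-subsequence oracle
#'
#' Exhaustively enumerates subsequences of the shorter input (longest
#' first) and returns the length of the longest one that is also a
#' subsequence of the other. Exponential in the sequence length: guarded
#' to lengths <= 12. Intended as an independent test oracle for
#' [nw_score()], not for production use.
#'
#' @inheritParams nw_score
#' @return Integer LCS length.
#' @export
lcs_oracle <- function(x_i, x_j) {
  for (s in c(x_i, x_j)) {
    if (nchar(s) > 12L) abort("lcs_oracle is limited to lengths <= 12.")
  }
  a <- strsplit(x_i, "", fixed = TRUE)[[1]]
  b <- strsplit(x_j, "", fixed = TRUE)[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  if (length(a) == 0L) return(0L)
  is_subseq <- function(sub, full) {
    j <- 1L
    for (ch in full) {
      if (j > length(sub)) break
      if (ch == sub[j]) j <- j + 1L
    }
    j > length(sub)
  }
  for (k in seq(length(a), 1L)) {
    for (pick in utils::combn(length(a), k, simplify = FALSE)) {
      if (is_subseq(a[pick], b)) return(k)
    }
  }
  0L
}

#' Pairwise similarity statistics of a labeled dataset
#'
#' Randomly samples a fraction of the `C(n, 2)` unordered sequence pairs
#' without replacement (default 0.01%), computes the normalized edit
#' similarity of each, and summarizes the relationship between similarity
#' and the supervised labels: per-interval pair counts (default interval
#' width 0.1, top interval closed), the positive-pair proportion per
#' interval, extreme similarities, and mean similarity of positive pairs
#' (same label) versus negative pairs (different labels). This is the
#' machinery used to pick the positive/negative thresholds of the
#' self-supervised pair labeling.
#'
#' @param d A labeled dataset tibble.
#' @param sample_fraction Fraction of unordered pairs to sample
#'   (default `1e-4`); a fraction yielding zero pairs is raised to one
#'   pair with a warning.
#' @param interval_width Histogram bin width in `(0, 1]`; default 0.1.
#' @param seed Integer seed for the pair sample.
#' @return An object of class `simstats`: a list with
#'   `sampled_pair_count`, `min_sim`, `max_sim`,
#'   `mean_sim_positive_pairs`, `mean_sim_negative_pairs`, and an
#'   `intervals` tibble (`interval`, `lower`, `upper`, `count`,
#'   `positive_count`, `positive_proportion`). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
pair_statistics <- function(d, sample_fraction = 1e-4, interval_width = 0.1,
                            seed = 1L) {
  d <- check_dataset(d)
  n <- nrow(d)
  if (n < 2L) abort("Need at least 2 records for pair statistics.")
  if (!(sample_fraction > 0 && sample_fraction <= 1)) {
    abort("`sample_fraction` must be in (0, 1].")
  }
  if (!(interval_width > 0 && interval_width <= 1)) {
    abort("`interval_width` must be in (0, 1].")
  }
  n_pairs_total <- n * (n - 1) / 2
  n_pairs <- round(sample_fraction * n_pairs_total)
  if (n_pairs < 1) {
    warn("Requested fraction yields 0 pairs; sampling 1 pair instead.")
    n_pairs <- 1
  }
  ks <- withr_seed(seed, sample_pair_indices(n_pairs_total, n_pairs))
  ij <- unrank_pairs(ks, n)
  sims <- sequence_similarity_many(d$sequence[ij[, 1]], d$sequence[ij[, 2]])
  same <- d$label[ij[, 1]] == d$label[ij[, 2]]

  n_bins <- ceiling(1 / interval_width - 1e-9)
  lower <- (seq_len(n_bins) - 1) * interval_width
  upper <- pmin(lower + interval_width, 1)
  bin <- pmin(floor(sims / interval_width) + 1, n_bins)  # top interval closed
  counts <- tabulate(bin, nbins = n_bins)
  pos_counts <- tabulate(bin[same], nbins = n_bins)

  structure(list(
    sampled_pair_count = length(sims),
    min_sim = min(sims),
    max_sim = max(sims),
    mean_sim_positive_pairs = if (any(same)) mean(sims[same]) else NA_real_,
    mean_sim_negative_pairs = if (any(!same)) mean(sims[!same]) else NA_real_,
    interval_width = interval_width,
    intervals = tibble(
      interval = sprintf("[%.2g,%.2g%s", lower, upper,
                         ifelse(upper >= 1, "]", ")")),
      lower = lower, upper = upper,
      count = counts, positive_count = pos_counts,
      positive_proportion = ifelse(counts > 0, pos_counts / counts, NA_real_)
    )
  ), class = "simstats")
}

# Sample `m` distinct values from 1..total (total may exceed .Machine's
# integer range; combinadic unranking keeps everything in doubles).
sample_pair_indices <- function(total, m) {
  if (total <= 2^31 - 1) {
    sort(sample.int(as.integer(total), m))
  } else {
    # rejection sampling on doubles for astronomically many pairs
    ks <- unique(ceiling(runif(m * 1.2 + 10) * total))
    while (length(ks) < m) {
      ks <- unique(c(ks, ceiling(runif(m) * total)))
    }
    sort(ks[seq_len(m)])
  }
}

# Map linear pair ranks 1..C(n,2) to unordered index pairs (i < j), rank
# ordered by i then j.
unrank_pairs <- function(ks, n) {
  # rank r of pair (i,j): (i-1)*n - i*(i+1)/2 + j
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * ks))
  base <- (i - 1) * n - i * (i + 1) / 2
  j <- ks - base
  # guard against floating-point edge cases
  fix <- j <= i | j > n
  if (any(fix)) {
    for (idx in which(fix)) {
      ii <- i[idx]
      while (TRUE) {
        base_i <- (ii - 1) * n - ii * (ii + 1) / 2
        jj <- ks[idx] - base_i
        if (jj > ii && jj <= n) { i[idx] <- ii; j[idx] <- jj; break }
        ii <- ii + if (jj <= ii) -1 else 1
      }
    }
  }
  cbind(as.integer(i), as.integer(j))
}

#' @export
print.simstats <- function(x, ...) {
  cat("Pairwise similarity statistics\n")
  cat(sprintf("  sampled pairs: %d\n", x$sampled_pair_count))
  cat(sprintf("  similarity range: [%.4f, %.4f]\n", x$min_sim, x$max_sim))
  cat(sprintf("  mean similarity, same-label pairs:      %.4f\n",
              x$mean_sim_positive_pairs))
  cat(sprintf("  mean similarity, different-label pairs: %.4f\n",
              x$mean_sim_negative_pairs))
  print(x$intervals)
  invisible(x)
}

#' @rdname pair_statistics
#' @param x,object A `simstats` object.
#' @param ... Unused.
#' @export
tidy.simstats <- function(x, ...) x$intervals

#' @rdname pair_statistics
#' @export
glance.simstats <- function(x, ...) {
  tibble(
    sampled_pair_count = x$sampled_pair_count,
    min_sim = x$min_sim, max_sim = x$max_sim,
    mean_sim_positive_pairs = x$mean_sim_positive_pairs,
    mean_sim_negative_pairs = x$mean_sim_negative_pairs
  )
}

#' @rdname pair_statistics
#' @export
autoplot.simstats <- function(object, ...) {
  dat <- object$intervals
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lower + object$interval_width / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70") +
    ggplot2::geom_point(
      data = dplyr::filter(dat, !is.na(.data$positive_proportion)),
      ggplot2::aes(y = .data$positive_proportion * max(dat$count)),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(
      "pair count",
      sec.axis = ggplot2::sec_axis(~ . / max(dat$count),
                                   name = "positive-pair proportion")
    ) +
    ggplot2::labs(x = "sequence similarity interval") +
    ggplot2::theme_minimal()
}
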