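#' Synthetic planted-motif configuration
#'
#' Parameters of the synthetic occupancy datasets: negatives are i.i.d.
#' uniform over `{A, C, G, T}`; positives are uniform background with one
#' mutated copy of the consensus motif planted at a uniformly random
#' offset. This emulates fixed-length motif-instance sets where only
#' bound (positive) sequences carry the binding signal; it does not model
#' genomic base composition, multiple binding sites, or positional bias.
#'
#' @param n_records Total number of records.
#' @param length Sequence length `L`; default 101.
#' @param motif Consensus motif over `{A, C, G, T}`; default the 8-mer
#'   `"TGACGTCA"`.
#' @param mutation_prob Per-position probability that a planted motif
#'   character is replaced by a uniformly chosen different token;
#'   default 0.1.
#' @param positive_fraction Class balance; default 0.5.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_records = 1000L, length = 101L,
                         motif = "TGACGTCA", mutation_prob = 0.1,
                         positive_fraction = 0.5, seed = 1L) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) abort("`motif` must be over {A,C,G,T}.")
  if (nchar(motif) > length) abort("`motif` longer than the sequence length.")
  stopifnot(n_records >= 1, mutation_prob >= 0, mutation_prob < 1,
            positive_fraction > 0, positive_fraction < 1)
  structure(list(n_records = as.integer(n_records), length = as.integer(length),
                 motif = motif, mutation_prob = mutation_prob,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)), class = "synth_config")
}

#' Generate a synthetic planted-motif dataset
#'
#' @param cfg A [synth_config()].
#' @return A labeled dataset tibble (`id`, `sequence`, `label`) with
#'   exactly `round(n_records * positive_fraction)` positives, in
#'   shuffled order. Seed-deterministic.
#' @examples
#' d <- generate_motif_dataset(synth_config(n_records = 10, seed = 42))
#' table(d$label)
#' @export
generate_motif_dataset <- function(cfg = synth_config()) {
  withr_seed(cfg$seed, {
    n <- cfg$n_records
    L <- cfg$length
    n_pos <- as.integer(round(n * cfg$positive_fraction))
    n_pos <- max(1L, min(n - 1L, n_pos))
    motif <- strsplit(cfg$motif, "", fixed = TRUE)[[1]]
    w <- length(motif)

    random_seq <- function() sample(DNA_TOKENS, L, replace = TRUE)
    seqs <- character(n)
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    for (i in seq_len(n)) {
      chars <- random_seq()
      if (labels[i] == 1L) {
        inst <- motif
        mut <- runif(w) < cfg$mutation_prob
        for (p in which(mut)) {
          inst[p] <- sample(setdiff(DNA_TOKENS, inst[p]), 1L)
        }
        off <- sample.int(L - w + 1L, 1L)
        chars[off:(off + w - 1L)] <- inst
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    ord <- sample.int(n)
    new_dna_dataset(id = sprintf("s%d", seq_len(n))[ord],
                    sequence = seqs[ord], label = labels[ord])
  })
}

#' Substring-count oracle classifier
#'
#' Scores each sequence by its maximum match count of the consensus motif
#' over all offsets (number of agreeing positions of the best window,
#' scaled to `[0, 1]`). With `mutation_prob = 0` this separates planted
#' positives from background almost perfectly, giving a known-answer
#' dataset for validating [evaluate()] and the training pipelines.
#'
#' @param d A dataset tibble.
#' @param motif Consensus motif string.
#' @return A tibble `id`, `label`, `y_pred`.
#' @export
motif_scan_scores <- function(d, motif = "TGACGTCA") {
  d <- check_dataset(d)
  motif_oh <- one_hot_encode(motif)
  w <- nchar(motif)
  scores <- vapply(d$sequence, function(s) {
    oh <- one_hot_encode(s)
    T_ <- nrow(oh) - w + 1L
    best <- 0
    for (t in seq_len(T_)) {
      best <- max(best, sum(oh[t:(t + w - 1L), ] * motif_oh))
    }
    best / w
  }, numeric(1), USE.NAMES = FALSE)
  tibble(id = d$id, label = d$label, y_pred = scores)
}
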