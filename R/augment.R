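#' Construct a single edit operation
#'
#' Length-preserving edit operations on fixed-length DNA sequences:
#' * `insert_delete` — insert `token` before 0-based position `ins_pos`
#'   (`ins_pos = L` appends), then delete the character at 0-based
#'   `del_pos` of the post-insertion sequence, so the length is unchanged;
#' * `substitute` — replace the character at `pos` with a different `token`;
#' * `delete_to_null` — replace the character at `pos` with the null
#'   token `N`.
#'
#' @param kind One of `"insert_delete"`, `"substitute"`, `"delete_to_null"`.
#' @param pos 0-based position (substitute / delete_to_null).
#' @param token Inserted or replacement character in `{A, C, G, T}`.
#' @param ins_pos,del_pos 0-based insertion and deletion positions for
#'   `insert_delete`; `del_pos` indexes the post-insertion sequence.
#' @return An object of class `edit_op`.
#' @export
edit_op <- function(kind = c("insert_delete", "substitute", "delete_to_null"),
                    pos = NULL, token = NULL, ins_pos = NULL, del_pos = NULL) {
  kind <- match.arg(kind)
  op <- list(kind = kind, pos = pos, token = token,
             ins_pos = ins_pos, del_pos = del_pos)
  if (kind %in% c("substitute", "insert_delete") &&
      (!is.character(token) || !token %in% DNA_TOKENS)) {
    abort("`token` must be one of A, C, G, T.")
  }
  structure(op, class = "edit_op")
}

#' Apply an edit operation to a sequence
#'
#' Applies a single length-preserving [edit_op()]; the result always has
#' the same length as the input.
#'
#' @param x A DNA sequence string.
#' @param op An [edit_op()].
#' @return The edited sequence string.
#' @examples
#' apply_edit("ACGT", edit_op("substitute", pos = 0, token = "T"))
#' apply_edit("ACGT", edit_op("delete_to_null", pos = 2))
#' apply_edit("ACGT", edit_op("insert_delete", ins_pos = 0, token = "G", del_pos = 4))
#' @export
apply_edit <- function(x, op) {
  x <- parse_sequence(x)
  if (!inherits(op, "edit_op")) abort("`op` must be an edit_op.")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- length(chars)
  check_pos <- function(p, upper, what) {
    if (is.null(p) || p < 0 || p > upper) {
      abort(sprintf("%s out of range [0, %d].", what, upper))
    }
  }
  out <- switch(op$kind,
    substitute = {
      check_pos(op$pos, L - 1L, "substitute position")
      if (chars[op$pos + 1L] == op$token) {
        abort("Substitution token must differ from the replaced character.")
      }
      chars[op$pos + 1L] <- op$token
      chars
    },
    delete_to_null = {
      check_pos(op$pos, L - 1L, "delete position")
      chars[op$pos + 1L] <- "N"
      chars
    },
    insert_delete = {
      check_pos(op$ins_pos, L, "insert position")
      check_pos(op$del_pos, L, "delete position")
      ins <- append(chars, op$token, after = op$ins_pos)
      ins[-(op$del_pos + 1L)]
    }
  )
  paste(out, collapse = "")
}

# Draw one random edit op for a length-L sequence; kind uniform over the
# three operation types, tokens uniform over {A,C,G,T}, substitution forced
# to change the character.
random_edit_op <- function(chars, L) {
  kind <- sample(c("insert_delete", "substitute", "delete_to_null"), 1L)
  switch(kind,
    substitute = {
      pos <- sample.int(L, 1L) - 1L
      cur <- chars[pos + 1L]
      token <- sample(setdiff(DNA_TOKENS, cur), 1L)
      edit_op("substitute", pos = pos, token = token)
    },
    delete_to_null = edit_op("delete_to_null", pos = sample.int(L, 1L) - 1L),
    insert_delete = edit_op("insert_delete",
                            ins_pos = sample.int(L + 1L, 1L) - 1L,
                            token = sample(DNA_TOKENS, 1L),
                            del_pos = sample.int(L + 1L, 1L) - 1L)
  )
}

#' Augmentation settings
#'
#' @param k_max_fraction Per-view edit budget as a fraction of the length:
#'   the op count is uniform on `{1, ..., floor(k_max_fraction * L)}`.
#'   Default 0.05, which for `L = 101` allows at most 5 ops per view and
#'   keeps sibling views above the 0.9 similarity floor in practice.
#' @param min_similarity Inter-view similarity floor enforced by
#'   resampling; default 0.9.
#' @param max_retries Resampling budget before erroring; default 100.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(k_max_fraction = 0.05, min_similarity = 0.9,
                           max_retries = 100L) {
  stopifnot(k_max_fraction > 0, min_similarity >= 0, min_similarity < 1,
            max_retries >= 1)
  structure(list(k_max_fraction = k_max_fraction,
                 min_similarity = min_similarity,
                 max_retries = max_retries), class = "augment_config")
}

#' Produce two augmented views of one sequence
#'
#' Draws two independent random edit programs (op counts uniform on
#' `{1, ..., floor(0.05 L)}` by default, each op a random
#' insertion+deletion, substitution, or deletion-to-null), applies them to
#' two copies of `x`, and verifies that the normalized edit similarity
#' between the two views exceeds `min_similarity` (default 0.9),
#' resampling both views afresh if not. Length is preserved exactly.
#'
#' @param x A DNA sequence of length >= 20 (so the op budget is >= 1).
#' @param config An [augment_config()].
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream (R's Mersenne-Twister).
#' @return A list of class `augmented_pair` with `view1`, `view2`,
#'   `ops1`, `ops2`, `similarity`.
#' @export
augment_pair <- function(x, config = augment_config(), seed = NULL) {
  x <- parse_sequence(x)
  L <- nchar(x)
  if (L < 20L) abort("Augmentation requires sequences of length >= 20.")
  withr_seed(seed, {
    k_max <- max(1L, floor(config$k_max_fraction * L))
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    draw_view <- function() {
      k <- sample.int(k_max, 1L)
      v <- x
      ops <- vector("list", k)
      for (t in seq_len(k)) {
        op <- random_edit_op(strsplit(v, "", fixed = TRUE)[[1]], L)
        ops[[t]] <- op
        v <- apply_edit(v, op)
      }
      list(view = v, ops = ops)
    }
    for (try in seq_len(config$max_retries)) {
      v1 <- draw_view()
      v2 <- draw_view()
      sim <- sequence_similarity(v1$view, v2$view)
      if (sim > config$min_similarity) {
        return(structure(list(view1 = v1$view, view2 = v2$view,
                              ops1 = v1$ops, ops2 = v2$ops,
                              similarity = sim), class = "augmented_pair"))
      }
    }
    abort("Augmentation retry budget exhausted; reduce `k_max_fraction`.")
  })
}

#' Augment a mini-batch into 2n ordered views
#'
#' For a batch of `n` labeled records, produces the `2n` augmented views
#' `(x_1^1, x_1^2, ..., x_n^1, x_n^2)`, each carrying its origin record
#' index and origin label for downstream pair labeling.
#'
#' @param batch A labeled dataset tibble (the mini-batch).
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `view`, `origin_index`, `origin_label`,
#'   `sequence` (2n rows).
#' @export
make_batch_views <- function(batch, config = augment_config(), seed = NULL) {
  batch <- check_dataset(batch)
  if (nrow(batch) < 1L) abort("Batch must contain at least one record.")
  withr_seed(seed, {
    pairs <- lapply(batch$sequence, augment_pair, config = config)
    tibble(
      view = rep(1:2, times = nrow(batch)),
      origin_index = rep(seq_len(nrow(batch)), each = 2L),
      origin_label = rep(batch$label, each = 2L),
      sequence = as.character(rbind(
        vapply(pairs, `[[`, character(1), "view1"),
        vapply(pairs, `[[`, character(1), "view2")
      ))
    )
  })
}
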