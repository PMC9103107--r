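#' Parse and validate a DNA sequence
#'
#' Uppercases the input and checks every character against the
#' `{A, C, G, T, N}` alphabet. `N` is the null/unknown base. Any other
#' character is an error (it is never silently mapped to `N`, which would
#' corrupt downstream similarity statistics).
#'
#' @param text A non-empty character scalar; lowercase `a/c/g/t/n` accepted.
#' @return A validated, uppercased character scalar.
#' @examples
#' parse_sequence("acgtn")
#' @export
parse_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty string.")
  }
  seq <- toupper(text)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid character '%s' at position %d (0-based); alphabet is {A,C,G,T,N}.",
      chars[bad[1]], bad[1] - 1L
    ))
  }
  seq
}

validate_sequences <- function(seqs, what = "sequence") {
  seqs <- toupper(seqs)
  ok <- grepl("^[ACGTN]+$", seqs)
  if (!all(ok)) {
    abort(sprintf("%d %s(s) contain characters outside {A,C,G,T,N}.",
                  sum(!ok), what))
  }
  seqs
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as an `L x 4` matrix with channel order `(A, T, C, G)`:
#' `A -> (1,0,0,0)`, `T -> (0,1,0,0)`, `C -> (0,0,1,0)`, `G -> (0,0,0,1)`.
#' The null token `N` maps to the all-zero row, so a row sums to 1 for a
#' known base and 0 for `N`.
#'
#' @param x A DNA sequence string (see [parse_sequence()]).
#' @return An integer `L x 4` matrix with columns named `A, T, C, G`.
#' @seealso [one_hot_decode()] for the inverse.
#' @examples
#' one_hot_encode("ATCGN")
#' @export
one_hot_encode <- function(x) {
  x <- parse_sequence(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- matrix(0L, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, ONEHOT_CHANNELS))
  hit <- match(chars, ONEHOT_CHANNELS)  # N -> NA -> zero row
  known <- which(!is.na(hit))
  m[cbind(known, hit[known])] <- 1L
  m
}

#' Decode a one-hot matrix back to a DNA sequence
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to `N`.
#'
#' @param m An `L x 4` 0/1 matrix in channel order `(A, T, C, G)`.
#' @return A DNA sequence string.
#' @export
one_hot_decode <- function(m) {
  if (!is.matrix(m) || ncol(m) != 4L) abort("`m` must be an L x 4 matrix.")
  rs <- rowSums(m)
  if (!all(rs %in% c(0, 1)) || !all(m %in% c(0, 1))) {
    abort("`m` must be one-hot: 0/1 entries with row sums 0 or 1.")
  }
  chars <- rep("N", nrow(m))
  hot <- which(rs == 1)
  chars[hot] <- ONEHOT_CHANNELS[max.col(m[hot, , drop = FALSE])]
  paste(chars, collapse = "")
}

# Batch one-hot encoding in the layout the encoder consumes: one row per
# sequence, 4 channels per position, position-major (column (p-1)*4 + c).
encode_batch <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  X <- matrix(0, nrow = n, ncol = 4L * L)
  for (ch in seq_along(ONEHOT_CHANNELS)) {
    hit <- chars == ONEHOT_CHANNELS[ch]
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      X[cbind(idx[, 1], (idx[, 2] - 1L) * 4L + ch)] <- 1
    }
  }
  X
}

new_dna_dataset <- function(id, sequence, label = NA_integer_) {
  tibble(id = as.character(id), sequence = sequence, label = as.integer(label))
}

check_dataset <- function(d, labeled = TRUE, arg = "data") {
  if (!is.data.frame(d) || !all(c("sequence") %in% names(d))) {
    abort(sprintf("`%s` must be a data frame with a `sequence` column.", arg))
  }
  d <- as_tibble(d)
  if (!"id" %in% names(d)) d$id <- sprintf("r%d", seq_len(nrow(d)))
  d$sequence <- validate_sequences(d$sequence)
  lens <- nchar(d$sequence)
  if (nrow(d) > 0L && length(unique(lens)) != 1L) {
    off <- d$id[lens != lens[1]]
    abort(sprintf(
      "All sequences must share one length; offending ids: %s",
      paste(utils::head(off, 5L), collapse = ", ")
    ))
  }
  if (labeled) {
    if (!"label" %in% names(d) || anyNA(d$label)) {
      abort("Dataset must carry a complete binary `label` column.")
    }
    d$label <- as.integer(d$label)
    if (!all(d$label %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  }
  d[c("id", "sequence", if ("label" %in% names(d)) "label")]
}

#' Read a labeled DNA sequence dataset
#'
#' Reads fixed-length labeled sequences from a 2-column TSV
#' (`<sequence>\t<label>`, optional header) or a FASTA file whose
#' description lines carry a `label=<0|1>` token. Gzipped files
#' (`.gz` extension) are handled transparently. Multi-column TSV dialects
#' are read by naming which columns hold the sequence and label via
#' `column_map`.
#'
#' @param path File path; `.gz` accepted.
#' @param format `"tsv"` or `"fasta"`; default guessed from the extension.
#' @param column_map Optional named list/vector for TSV dialects with extra
#'   columns, e.g. `c(sequence = 2, label = 3)` (positions) or
#'   `c(sequence = "seq", label = "bound")` (header names). Optionally an
#'   `id` entry.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ACGT\t1", "TTTT\t0"), tf)
#' read_dataset(tf)
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "fasta"),
                         column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) "fasta" else "tsv"
  }
  d <- if (format == "fasta") read_dataset_fasta(path) else
    read_dataset_tsv(path, column_map)
  check_dataset(d)
}

read_dataset_tsv <- function(path, column_map = NULL) {
  has_header <- tsv_has_header(path)
  tab <- readr::read_tsv(path, col_names = has_header$names,
                         col_types = readr::cols(.default = readr::col_character()),
                         skip = has_header$skip, progress = FALSE)
  pick <- function(role, default) {
    sel <- if (!is.null(column_map) && role %in% names(column_map))
      column_map[[role]] else default
    if (is.null(sel)) return(NULL)
    if (is.character(sel)) {
      if (!sel %in% names(tab)) abort(sprintf("Column '%s' not found.", sel))
      tab[[sel]]
    } else tab[[as.integer(sel)]]
  }
  seqs <- pick("sequence", 1L)
  labs <- pick("label", 2L)
  if (is.null(labs) || anyNA(suppressWarnings(as.integer(labs)))) {
    abort("Missing or non-numeric label column; use `column_map` for multi-column files.")
  }
  ids <- pick("id", NULL)
  new_dna_dataset(
    id = if (is.null(ids)) sprintf("r%d", seq_len(nrow(tab))) else ids,
    sequence = seqs, label = as.integer(labs)
  )
}

# A header line is one whose putative sequence field is not a DNA string.
tsv_has_header <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  looks_data <- any(grepl("^[ACGTNacgtn]+$", fields))
  if (looks_data) list(names = FALSE, skip = 0L)
  else list(names = TRUE, skip = 0L)
}

read_dataset_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  desc <- names(ss)
  m <- regmatches(desc, regexpr("label=([01])", desc))
  if (length(m) != length(desc) || any(!nzchar(m))) {
    abort("Every FASTA description must carry a 'label=<0|1>' token.")
  }
  labs <- as.integer(sub("label=", "", m, fixed = TRUE))
  ids <- vapply(strsplit(desc, "\\s+"), `[[`, character(1), 1L)
  new_dna_dataset(id = ids, sequence = as.character(ss), label = labs)
}

#' Write a labeled dataset to TSV or FASTA
#'
#' The canonical on-disk format is the 2-column TSV
#' (`<sequence>\t<label>`, no header); FASTA output writes
#' `><id> label=<0|1>` description lines. A `.gz` path compresses.
#'
#' @param d A dataset tibble (columns `sequence`, `label`, optional `id`).
#' @param path Output path.
#' @param format `"tsv"` or `"fasta"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  d <- check_dataset(d)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) "fasta" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(d[c("sequence", "label")], path, col_names = FALSE,
                     progress = FALSE)
  } else {
    ss <- Biostrings::BStringSet(setNames(d$sequence, sprintf("%s label=%d", d$id, d$label)))
    Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Split a dataset into training and validation parts
#'
#' Random, seed-deterministic partition holding out `round(fraction * n)`
#' records for validation (default 1/8, the conventional hold-out for
#' model selection in this pipeline).
#'
#' @param d A dataset tibble.
#' @param fraction Validation proportion in (0, 1); default `1/8`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `validation`.
#' @export
split_train_validation <- function(d, fraction = 1 / 8, seed = 1L) {
  d <- check_dataset(d)
  n <- nrow(d)
  if (n < 2L) abort("Need at least 2 records to split.")
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must be in (0, 1).")
  n_val <- max(1L, as.integer(round(fraction * n)))
  if (n_val >= n) n_val <- n - 1L
  idx <- withr_seed(seed, sample.int(n, n_val))
  list(train = d[-idx, , drop = FALSE], validation = d[idx, , drop = FALSE])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards (seed = NULL uses the current stream).
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
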