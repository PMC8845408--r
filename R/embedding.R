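#' Tokenize a protein sequence into overlapping k-mers
#'
#' Breaks a sequence into its `nchar(sequence) - k + 1` overlapping
#' length-`k` windows at stride 1, the "words" of the protein embedding.
#'
#' @param sequence Amino-acid string of length >= `k`.
#' @param k Window length in residues (default 3).
#' @param id Optional identifier used in error messages.
#' @return Character vector of k-mers, in sequence order.
#' @examples
#' tokenize_kmers("MKVLA", 3)
#' @export
tokenize_kmers <- function(sequence, k = 3L, id = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  n <- nchar(sequence)
  if (n < k) {
    stop("sequence ", if (!is.null(id)) paste0("'", id, "' "),
         "is shorter (", n, ") than k (", k, ")")
  }
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Train skip-gram k-mer embeddings on a protein corpus
#'
#' Tokenizes every corpus sequence into overlapping k-mers and trains
#' word2vec-style skip-gram vectors with hierarchical softmax.  The trainer
#' is single-threaded and fully seeded, so the returned vectors are
#' reproducible.  Defaults follow the embedding recipe this package
#' implements: k = 3, 200 dimensions, context window 8.
#'
#' @param corpus Protein record data frame (every sequence must have length
#'   >= `k`).
#' @param k K-mer length.
#' @param d_model Embedding dimension.
#' @param window Skip-gram context window.
#' @param epochs Training passes over the corpus.
#' @param alpha Initial learning rate (linearly decayed).
#' @param min_count Minimum corpus frequency for a k-mer to enter the
#'   vocabulary.
#' @param seed Integer training seed.
#' @return An object of class `embedding_model`: list with `vectors` (a
#'   vocabulary x `d_model` matrix with k-mer rownames), `k`, `d_model`,
#'   `window`, `epochs`, `alpha`, `min_count`, `seed` and
#'   `algorithm = "skipgram_hs"`.
#' @export
train_skipgram <- function(corpus, k = 3L, d_model = 200L, window = 8L,
                           epochs = 5L, alpha = 0.025, min_count = 1L,
                           seed = 1L) {
  if (nrow(corpus) == 0) stop("empty corpus")
  if (d_model < 1) stop("d_model must be >= 1")
  sentences_chr <- lapply(seq_len(nrow(corpus)), function(i) {
    tokenize_kmers(corpus$sequence[i], k, id = corpus$id[i])
  })
  counts <- table(unlist(sentences_chr))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("no k-mer reaches min_count")
  # word2vec vocabulary order: frequency-descending, alphabetical tie-break
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  vcount <- as.numeric(counts)[ord]
  lookup <- stats::setNames(seq_along(vocab), vocab)
  sentences <- lapply(sentences_chr, function(toks) {
    ids <- lookup[toks]
    as.integer(ids[!is.na(ids)]) - 1L   # 0-based; OOV-by-min-count dropped
  })
  vec <- .sg_train_cpp(sentences, vcount, as.integer(d_model),
                       as.integer(window), as.integer(epochs),
                       alpha, as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vectors = vec, k = as.integer(k),
                 d_model = as.integer(d_model), window = as.integer(window),
                 epochs = as.integer(epochs), alpha = alpha,
                 min_count = as.integer(min_count), seed = as.integer(seed),
                 algorithm = "skipgram_hs"),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf(
    "<embedding_model> %d k-mers (k=%d), %d dims, window %d, %s, seed %d\n",
    nrow(x$vectors), x$k, x$d_model, x$window, x$algorithm, x$seed))
  invisible(x)
}

#' Sinusoidal positional encoding
#'
#' Deterministic order signal for position `pos`: dimension pairs
#' `(2i, 2i+1)` (0-based) hold `sin(pos / base^(2i/d_model))` and
#' `cos(pos / base^(2i/d_model))`.  Wavelengths form a geometric
#' progression from `2*pi` to `base * 2*pi` across pairs, and each pair
#' lies on the unit circle, so `PE(pos + delta)` is a fixed per-pair
#' rotation of `PE(pos)`.
#'
#' @param pos 0-based position index (scalar or vector).
#' @param d_model Even encoding dimension.
#' @param base Wavelength constant (default 10000).
#' @return For scalar `pos` a numeric vector of length `d_model`; for
#'   vector `pos` a `length(pos) x d_model` matrix.
#' @examples
#' positional_encoding(0, 8)
#' @export
positional_encoding <- function(pos, d_model, base = 10000) {
  d_model <- as.integer(d_model)
  if (d_model < 2 || d_model %% 2L != 0L) {
    stop("d_model must be even and >= 2")
  }
  if (any(pos < 0)) stop("pos must be >= 0")
  i <- seq_len(d_model %/% 2L) - 1L
  freq <- 1 / base^(2 * i / d_model)
  ang <- outer(pos, freq)                       # |pos| x d_model/2
  out <- matrix(0, nrow = length(pos), ncol = d_model)
  out[, 2L * i + 1L] <- sin(ang)
  out[, 2L * i + 2L] <- cos(ang)
  if (length(pos) == 1L) drop(out) else out
}

#' Embed one tokenized protein as a fixed-length vector
#'
#' Averages the k-mer vectors over token positions.  With `use_pe = TRUE`
#' each token vector is modulated elementwise by its position's sinusoidal
#' encoding before averaging:
#' `mean over t of v_t * (1 + PE(t))`, which expands to the plain
#' compositional mean plus the order-dependent cross-term
#' `mean(v_t * PE(t))`.  The modulation (rather than pure addition of PE
#' followed by a mean) is deliberate: the positional term of an additive
#' mean, `mean(PE(t))`, depends only on sequence length, so a plain
#' additive mean is invariant under any reordering of the tokens and could
#' not carry sequence-order information into the fixed-length vector.
#' Out-of-vocabulary tokens contribute a zero vector but still occupy
#' their position (they count in the mean denominator).
#'
#' @param tokens Character vector of k-mers (from [tokenize_kmers()]).
#' @param model An `embedding_model`.
#' @param use_pe Add sinusoidal positional encodings before averaging.
#' @return Numeric vector of length `model$d_model` with attribute
#'   `oov_rate` (fraction of out-of-vocabulary tokens).
#' @export
embed_protein <- function(tokens, model, use_pe = TRUE) {
  stopifnot(inherits(model, "embedding_model"))
  n <- length(tokens)
  if (n == 0) stop("no tokens to embed")
  idx <- match(tokens, rownames(model$vectors))
  oov <- is.na(idx)
  if (all(oov) && !use_pe) {
    stop("no embeddable content: all ", n, " tokens out of vocabulary")
  }
  mat <- matrix(0, nrow = n, ncol = model$d_model)
  mat[!oov, ] <- model$vectors[idx[!oov], , drop = FALSE]
  if (use_pe) {
    pe <- positional_encoding(seq_len(n) - 1L, model$d_model)
    if (n == 1L) pe <- matrix(pe, nrow = 1L)
    mat <- mat * (1 + pe)
  }
  structure(colMeans(mat), oov_rate = mean(oov))
}

#' Embed a collection of protein records
#'
#' Convenience wrapper: tokenizes and embeds every record, returning a
#' feature matrix suitable for the classifiers.
#'
#' @param records Protein record data frame.
#' @param model An `embedding_model`.
#' @param use_pe Add positional encodings (see [embed_protein()]).
#' @return `nrow(records) x d_model` numeric matrix with `records$id` as
#'   rownames, `scheme` attribute `"W2V_PE"` or `"W2V"`, and `oov_rate`
#'   attribute (per-record vector).
#' @export
embed_records <- function(records, model, use_pe = TRUE) {
  out <- matrix(0, nrow = nrow(records), ncol = model$d_model,
                dimnames = list(records$id, NULL))
  oov <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- embed_protein(
      tokenize_kmers(records$sequence[i], model$k, id = records$id[i]),
      model, use_pe = use_pe)
    out[i, ] <- v
    oov[i] <- attr(v, "oov_rate")
  }
  structure(out, scheme = if (use_pe) "W2V_PE" else "W2V", oov_rate = oov)
}

#' Composition-plus-length baseline features
#'
#' The 21-dimensional baseline encoding: the fraction of each of the 20
#' standard amino acids (fixed order ACDEFGHIKLMNPQRSTVWY) followed by the
#' raw sequence length.  `X` residues count toward the length but toward no
#' amino-acid fraction.  Order-invariant by construction.
#'
#' @param sequence Non-empty amino-acid string.
#' @return Named numeric vector of length 21 (`A` ... `Y`, `length`).
#' @examples
#' comlen_features("ACDEFGHIKLMNPQRSTVWY")
#' @export
comlen_features <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  res <- strsplit(sequence, "")[[1]]
  counts <- table(factor(res, levels = AA_STANDARD))
  c(stats::setNames(as.numeric(counts) / n, AA_STANDARD), length = n)
}

#' Com-Len feature matrix for a record collection
#' @param records Protein record data frame.
#' @return `nrow(records) x 21` matrix with ids as rownames and `scheme`
#'   attribute `"COM_LEN"`.
#' @export
comlen_records <- function(records) {
  out <- t(vapply(records$sequence, comlen_features, numeric(21)))
  rownames(out) <- records$id
  structure(out, scheme = "COM_LEN")
}

#' Persist an embedding model as plain text
#'
#' Writes the model as a two-file pair: `<path>` in word2vec text format
#' (header line "V D", then one k-mer and D floats per line) and
#' `<path>.meta` as flat `key=value` training metadata.
#'
#' @param model An `embedding_model`.
#' @param path Output path for the vector table.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, open = "wt")
  writeLines(sprintf("%d %d", nrow(model$vectors), model$d_model), con)
  for (i in seq_len(nrow(model$vectors))) {
    writeLines(paste(rownames(model$vectors)[i],
                     paste(sprintf("%.17g", model$vectors[i, ]),
                           collapse = " ")), con)
  }
  close(con)
  meta <- c(k = model$k, d_model = model$d_model, window = model$window,
            epochs = model$epochs, alpha = model$alpha,
            min_count = model$min_count, seed = model$seed,
            algorithm = model$algorithm)
  writeLines(paste0(names(meta), "=", meta), paste0(path, ".meta"))
  invisible(path)
}

#' Load an embedding model written by [write_embedding()]
#' @param path Path to the vector table (sidecar `<path>.meta` must exist).
#' @return An `embedding_model`.
#' @export
read_embedding <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop("embedding model files not found at ", path, "(.meta)")
  }
  kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 2),
                          vapply(kv, `[[`, character(1), 1))
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(trimws(lines[-1]), " +")
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vec) <- vapply(parts, `[[`, character(1), 1)
  structure(list(vectors = vec, k = as.integer(meta[["k"]]),
                 d_model = as.integer(meta[["d_model"]]),
                 window = as.integer(meta[["window"]]),
                 epochs = as.integer(meta[["epochs"]]),
                 alpha = as.numeric(meta[["alpha"]]),
                 min_count = as.integer(meta[["min_count"]]),
                 seed = as.integer(meta[["seed"]]),
                 algorithm = meta[["algorithm"]]),
            class = "embedding_model")
}
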