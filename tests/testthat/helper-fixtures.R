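# Shared fixture builders.  Everything is generated in code under fixed
# seeds; nothing is read from disk.

# small, fast generator settings for unit tests
small_config <- function(seed = 101, ...) {
  args <- list(seed = seed, n_pos = 20L, n_neg = 40L,
               length_range = c(60L, 120L), corpus_size = 40L)
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

# two well-separated Gaussian blobs (separation ~10 sd): every algorithm
# must classify the training points perfectly
toy_blobs <- function(n_per_class = 50, seed = 7) {
  set.seed(seed)
  pos <- cbind(rnorm(n_per_class, 10), rnorm(n_per_class, 10))
  neg <- cbind(rnorm(n_per_class, 0), rnorm(n_per_class, 0))
  rownames(pos) <- sprintf("p%03d", seq_len(n_per_class))
  rownames(neg) <- sprintf("n%03d", seq_len(n_per_class))
  list(pos = pos, neg = neg)
}

toy_dataset <- function(n_per_class = 50, seed = 7) {
  b <- toy_blobs(n_per_class, seed)
  build_dataset(b$pos, b$neg, c(1L, 1L), seed = seed)
}

# corpus where "RGG" and "GGR" occur in interchangeable contexts while
# "WWW" lives in a disjoint context alphabet
contrast_corpus <- function(seed) {
  set.seed(seed)
  ctx <- function(alphabet, n) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  }
  hydro <- c("A", "V", "L")
  acidic <- c("K", "E", "D")
  seqs <- c(
    vapply(1:20, function(i) paste0(ctx(hydro, 15), "RGG", ctx(hydro, 15)),
           character(1)),
    vapply(1:20, function(i) paste0(ctx(hydro, 15), "GGR", ctx(hydro, 15)),
           character(1)),
    vapply(1:20, function(i) paste0(ctx(acidic, 15), "WWW", ctx(acidic, 15)),
           character(1)))
  protein_records(sprintf("c%02d", seq_along(seqs)), seqs)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# a small trained embedding shared across test files (trained once per run)
tiny_embedding <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      cache <<- train_skipgram(generate_corpus(cfg), d_model = 16L,
                               epochs = 2L, seed = 101L)
    }
    cache
  }
})
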