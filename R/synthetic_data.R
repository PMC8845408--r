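#' Default residue frequencies for synthetic positives
#'
#' Phase-separating proteins are enriched in low-complexity, RGG-like
#' composition; the default positive class therefore up-weights G, R, S, Y
#' and Q roughly three-fold over the remaining residues, with a trace of the
#' ambiguity letter 'X'.  Negatives use a near-uniform distribution over the
#' 20 standard residues with the same trace of 'X'.
#'
#' @param favored Residues to up-weight.
#' @param weight Relative weight of favored residues.
#' @param x_freq Frequency assigned to 'X'.
#' @return Named numeric probability vector over the 21-letter alphabet.
#' @export
positive_alphabet_bias <- function(favored = c("G", "R", "S", "Y", "Q"),
                                   weight = 3, x_freq = 0.005) {
  w <- stats::setNames(rep(1, 20), AA_STANDARD)
  w[favored] <- weight
  p <- w / sum(w) * (1 - x_freq)
  c(p, X = x_freq)
}

#' Near-uniform residue frequencies for synthetic negatives
#' @inheritParams positive_alphabet_bias
#' @return Named numeric probability vector over the 21-letter alphabet.
#' @export
uniform_alphabet_bias <- function(x_freq = 0.005) {
  p <- stats::setNames(rep((1 - x_freq) / 20, 20), AA_STANDARD)
  c(p, X = x_freq)
}

#' Configuration for the synthetic sequence generator
#'
#' Bundles every tunable of the fixture generator: class sizes, length
#' range, the planted sequence motif and its copy number, the residue
#' composition of each class, and the size of the unlabeled embedding
#' corpus.  The planted motif gives the positive class a *sequential*
#' signal (exact k-mer order) on top of the *compositional* signal from the
#' biased residue distribution.  With `decoy_in_negatives = TRUE` each
#' negative receives the same number of residue-permuted motif copies, so
#' the two classes match in composition and only sequence order separates
#' them.
#'
#' @param seed Integer seed; all sub-generators derive from it.
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer pair, inclusive residue-length range.
#' @param positive_motif Amino-acid motif planted into positives.
#' @param motif_repeats Number of non-overlapping motif copies per positive.
#' @param positive_alphabet_bias,negative_alphabet_bias Named probability
#'   vectors over the 21-letter alphabet (must sum to 1 within 1e-9).
#' @param corpus_size Number of unlabeled corpus sequences.
#' @param decoy_in_negatives Plant shuffled motif copies into negatives so
#'   the classes match compositionally.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_pos = 200L,
                             n_neg = 1000L,
                             length_range = c(100L, 400L),
                             positive_motif = "RGGRGG",
                             motif_repeats = 4L,
                             positive_alphabet_bias =
                               phasepred::positive_alphabet_bias(),
                             negative_alphabet_bias =
                               uniform_alphabet_bias(),
                             corpus_size = 1000L,
                             decoy_in_negatives = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg),
              length_range = as.integer(length_range),
              positive_motif = toupper(positive_motif),
              motif_repeats = as.integer(motif_repeats),
              positive_alphabet_bias = positive_alphabet_bias,
              negative_alphabet_bias = negative_alphabet_bias,
              corpus_size = as.integer(corpus_size),
              decoy_in_negatives = isTRUE(decoy_in_negatives))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(length(cfg$length_range) == 2,
            cfg$length_range[1] >= 1,
            cfg$length_range[1] <= cfg$length_range[2],
            cfg$n_pos >= 0, cfg$n_neg >= 0, cfg$corpus_size >= 0,
            cfg$motif_repeats >= 0)
  for (nm in c("positive_alphabet_bias", "negative_alphabet_bias")) {
    p <- cfg[[nm]]
    if (!setequal(names(p), AA_FULL)) {
      stop(nm, " must be named over the 21-letter alphabet")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " probabilities must be non-negative and sum to 1 (1e-9)")
    }
  }
  m <- nchar(cfg$positive_motif)
  if (cfg$motif_repeats > 0 && m * cfg$motif_repeats > cfg$length_range[1]) {
    stop("motif_repeats x motif length (", m * cfg$motif_repeats,
         ") exceeds minimum sequence length (", cfg$length_range[1], ")")
  }
  if (m > 0 &&
      grepl(sprintf("[^%s]", paste(AA_FULL, collapse = "")),
            cfg$positive_motif)) {
    stop("positive_motif contains non-alphabet characters")
  }
  invisible(cfg)
}

# Runs `expr` under a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards so generation never perturbs user code.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(expr)
}

random_sequence <- function(len, bias) {
  paste(sample(names(bias), len, replace = TRUE, prob = bias), collapse = "")
}

# Overwrites the given equal-length motifs at uniformly chosen, jointly
# non-overlapping start positions; sequence length is unchanged.
plant_motifs <- function(sequence, motifs) {
  motifs <- motifs[nchar(motifs) > 0]
  r <- length(motifs)
  if (r == 0) return(sequence)
  m <- nchar(motifs[1])
  stopifnot(all(nchar(motifs) == m))
  L <- nchar(sequence)
  # uniform non-overlapping placement: choose sorted slots in the
  # gap-compressed coordinate system, then re-expand
  slots <- sort(sample.int(L - r * m + r, r))
  starts <- slots + (seq_len(r) - 1) * (m - 1)
  for (i in seq_len(r)) {
    substr(sequence, starts[i], starts[i] + m - 1) <- motifs[i]
  }
  sequence
}

plant_motif <- function(sequence, motif, repeats) {
  if (repeats == 0 || nchar(motif) == 0) return(sequence)
  plant_motifs(sequence, rep(motif, repeats))
}

scramble <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Generate labeled positive and negative sequence sets
#'
#' Positives are drawn from the positive residue distribution with
#' `motif_repeats` non-overlapping copies of the motif overwritten at random
#' positions; negatives are drawn from the negative distribution (optionally
#' with residue-permuted motif decoys).  Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with protein record data frames `positives` (ids `pos_*`)
#'   and `negatives` (ids `neg_*`).
#' @export
generate_labeled_sets <- function(config) {
  validate_generator_config(config)
  with_private_seed(config$seed, {
    lens_p <- sample(config$length_range[1]:config$length_range[2],
                     config$n_pos, replace = TRUE)
    pos <- vapply(lens_p, function(L) {
      plant_motif(random_sequence(L, config$positive_alphabet_bias),
                  config$positive_motif, config$motif_repeats)
    }, character(1))
    lens_n <- sample(config$length_range[1]:config$length_range[2],
                     config$n_neg, replace = TRUE)
    neg <- vapply(lens_n, function(L) {
      s <- random_sequence(L, config$negative_alphabet_bias)
      if (config$decoy_in_negatives && config$motif_repeats > 0) {
        decoys <- vapply(seq_len(config$motif_repeats),
                         function(i) scramble(config$positive_motif),
                         character(1))
        s <- plant_motifs(s, decoys)
      }
      s
    }, character(1))
    list(positives = protein_records(sprintf("pos_%04d", seq_len(config$n_pos)),
                                     pos),
         negatives = protein_records(sprintf("neg_%04d", seq_len(config$n_neg)),
                                     neg))
  })
}

#' Generate an unlabeled embedding-training corpus
#'
#' Sequences are drawn from an equal mixture of the positive-style generator
#' (bias plus planted motif) and the negative-style generator, so the k-mer
#' vocabularies of both classes are covered as the corpus grows.
#' Deterministic given `config$seed`.
#'
#' @param config A [generator_config()] with `corpus_size >= 1`.
#' @return A protein record data frame with ids `corpus_*`.
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  if (config$corpus_size < 1) {
    stop("corpus_size must be >= 1")
  }
  with_private_seed(config$seed + 1L, {
    seqs <- vapply(seq_len(config$corpus_size), function(i) {
      L <- sample(config$length_range[1]:config$length_range[2], 1)
      if (stats::runif(1) < 0.5) {
        plant_motif(random_sequence(L, config$positive_alphabet_bias),
                    config$positive_motif, config$motif_repeats)
      } else {
        random_sequence(L, config$negative_alphabet_bias)
      }
    }, character(1))
    protein_records(sprintf("corpus_%05d", seq_len(config$corpus_size)), seqs)
  })
}

#' Randomly shuffle each sequence a fixed number of times
#'
#' Produces, for every input record, `n_shuffles` uniform random
#' permutations of its residues.  Shuffling preserves length and residue
#' multiset (hence all composition features) while destroying sequence
#' order, which makes it the control for order-sensitive encodings.
#'
#' @param records Protein record data frame.
#' @param n_shuffles Permutations per input sequence (>= 1).
#' @param seed Integer seed.
#' @return Protein record data frame of `nrow(records) * n_shuffles` rows
#'   with ids `<source id>_shuf<j>`; `source_id` column tracks provenance.
#' @export
shuffle_sequences <- function(records, n_shuffles, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (nrow(records) == 0) {
    out <- protein_records(character(0), character(0))
    out$source_id <- character(0)
    return(out)
  }
  with_private_seed(seed, {
    ids <- character(nrow(records) * n_shuffles)
    seqs <- character(length(ids))
    src <- character(length(ids))
    idx <- 1L
    for (i in seq_len(nrow(records))) {
      for (j in seq_len(n_shuffles)) {
        ids[idx] <- sprintf("%s_shuf%03d", records$id[i], j)
        seqs[idx] <- scramble(records$sequence[i])
        src[idx] <- records$id[i]
        idx <- idx + 1L
      }
    }
    out <- protein_records(ids, seqs)
    out$source_id <- src
    out
  })
}
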