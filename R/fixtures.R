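.rand_seq <- function(n, len, alphabet = c("A", "C", "G", "U"),
                      prob = NULL) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = ""),
    "")
}

.rna_comp <- c(A = "U", C = "G", G = "C", U = "A")

#' Synthetic positive- and negative-like hairpin records
#'
#' Positives are designed stem-loops: a random 5' arm (optionally GC-biased
#' so the stem is stable), a random terminal loop and the perfectly
#' complementary 3' arm; they fold into extractable hairpins by
#' construction. Negatives are residue-shuffled copies, emulating the
#' contrast between genuine precursor hairpins and hairpin-free decoys.
#'
#' @param n_pos,n_neg record counts.
#' @param stem_len stem arm length in bp (default 20).
#' @param loop_len terminal loop length in nt (default 6).
#' @param gc_bias probability mass on G/C in the stem arm (default 0.8).
#' @param seed integer seed; output is reproducible bit-identically.
#' @return list with `positive` and `negative` `hairpin_records`.
#' @export
make_hairpin_sequences <- function(n_pos, n_neg, stem_len = 20L,
                                   loop_len = 6L, gc_bias = 0.8, seed = 1L) {
  len <- 2L * stem_len + loop_len
  if (len < 36L || len > 180L)
    stop("geometry gives hairpin length ", len, ", outside [36, 180]")
  .with_seed(seed, {
    p <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
    mk <- function(i) {
      arm <- sample(c("A", "C", "G", "U"), stem_len, replace = TRUE, prob = p)
      loop <- sample(c("A", "C", "G", "U"), loop_len, replace = TRUE)
      paste(c(arm, loop, rev(unname(.rna_comp[arm]))), collapse = "")
    }
    pos_seq <- vapply(seq_len(n_pos), mk, "")
    pos <- hairpin_records(pos_seq, id = sprintf("pos_%03d", seq_len(n_pos)),
                           label = "positive", source = "fixture")
    neg_seq <- vapply(seq_len(max(n_neg, 0L)), function(i) {
      base <- if (n_pos) pos_seq[((i - 1L) %% n_pos) + 1L]
              else .rand_seq(1L, len)
      paste(sample(strsplit(base, "")[[1]]), collapse = "")
    }, "")
    neg <- hairpin_records(neg_seq, id = sprintf("neg_%03d", seq_len(n_neg)),
                           label = "negative", source = "fixture")
    list(positive = pos, negative = neg)
  })
}

#' Two separable Gaussian feature clouds
#'
#' Positive rows are drawn N(0, 1) per feature and negative rows
#' N(separation, 1), so the class mean distance equals `separation` pooled
#' standard deviations on every feature. `separation = 0` is the no-signal
#' null; `separation = 4` gives near-perfectly separable classes.
#'
#' @param n_pos,n_neg row counts.
#' @param n_features feature count (default 10).
#' @param separation standardized effect size (>= 0).
#' @param seed integer seed.
#' @return list of matrices `positive`, `negative` with feature columns
#'   `f01`.. and rowname ids.
#' @export
make_separable_features <- function(n_pos, n_neg, n_features = 10L,
                                    separation = 4, seed = 1L) {
  stopifnot(separation >= 0)
  .with_seed(seed, {
    fn <- sprintf("f%02d", seq_len(n_features))
    pos <- matrix(stats::rnorm(n_pos * n_features), nrow = n_pos,
                  dimnames = list(sprintf("pos_%04d", seq_len(n_pos)), fn))
    neg <- matrix(stats::rnorm(n_neg * n_features, mean = separation),
                  nrow = n_neg,
                  dimnames = list(sprintf("neg_%04d", seq_len(n_neg)), fn))
    list(positive = pos, negative = neg)
  })
}

#' Synthetic chromosome with planted hairpins
#'
#' A uniform-composition DNA background with `n_hairpins` designed
#' stem-loops (perfect GC stems by default, so the planted fold dominates
#' the background) inserted at non-overlapping random loci on random
#' strands. The returned truth table gives the planted loci in BED-style
#' 0-based half-open coordinates.
#'
#' @param genome_length chromosome length in nt (default 10000).
#' @param n_hairpins planted hairpin count (default 5).
#' @param stem_len,loop_len planted hairpin geometry (defaults 20/6).
#' @param seed integer seed.
#' @param chrom chromosome name (default "chrS").
#' @return list with `genome` (named DNA string) and `truth` (data.frame
#'   `chrom`, `start`, `end`, `name`, `strand`).
#' @export
make_synthetic_genome <- function(genome_length = 10000L, n_hairpins = 5L,
                                  stem_len = 20L, loop_len = 6L, seed = 1L,
                                  chrom = "chrS") {
  footprint <- 2L * stem_len + loop_len
  if (genome_length < n_hairpins * (footprint + 2L))
    stop("genome too short for ", n_hairpins, " planted hairpins")
  .with_seed(seed, {
    bg <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
                collapse = "")
    # non-overlapping loci via rejection sampling
    starts <- integer(0)
    guard <- 0L
    while (length(starts) < n_hairpins) {
      s <- sample.int(genome_length - footprint, 1L)
      if (all(abs(s - starts) >= footprint)) starts <- c(starts, s)
      guard <- guard + 1L
      if (guard > 10000L) stop("could not place non-overlapping hairpins")
    }
    starts <- sort(starts)
    strands <- sample(c("+", "-"), n_hairpins, replace = TRUE)
    genome <- bg
    for (h in seq_len(n_hairpins)) {
      arm <- sample(c("G", "C"), stem_len, replace = TRUE)
      loop <- sample(c("A", "T"), loop_len, replace = TRUE)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      hp <- paste(c(arm, loop, rev(unname(comp[arm]))), collapse = "")
      if (strands[h] == "-") hp <- revcomp_dna(hp)
      substr(genome, starts[h], starts[h] + footprint - 1L) <- hp
    }
    truth <- data.frame(chrom = chrom, start = starts - 1L,
                        end = starts - 1L + footprint,
                        name = sprintf("planted_%d", seq_len(n_hairpins)),
                        strand = strands)
    list(genome = stats::setNames(genome, chrom), truth = truth)
  })
}
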