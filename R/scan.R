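#' Fragment chromosomes into overlapping windows
#'
#' Sliding windows of `window` nt every `step` nt (0-based half-open
#' coordinates). A trailing fragment shorter than the window is kept when it
#' is at least `min_keep` nt (otherwise no hairpin could fit) and listed in
#' the `dropped` attribute when discarded.
#'
#' @param chroms named character vector of DNA chromosome sequences.
#' @param window window length (default 500).
#' @param step step between window starts (default 250).
#' @param min_keep minimum trailing-fragment length to keep (default 36).
#' @return data.frame `chrom`, `start`, `end`, `seq` (DNA).
#' @export
fragment_genome <- function(chroms, window = 500L, step = 250L,
                            min_keep = 36L) {
  stopifnot(window > step, step > 0)
  if (is.null(names(chroms))) names(chroms) <- paste0("chr", seq_along(chroms))
  rows <- list(); dropped <- list()
  for (cn in names(chroms)) {
    L <- nchar(chroms[[cn]])
    if (L == 0L) next
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    for (s in starts) {
      e <- min(s + window, L)
      if (e - s < window && e - s < min_keep) {
        dropped[[length(dropped) + 1L]] <- c(chrom = cn, start = s, end = e)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = cn, start = s, end = e,
                   seq = substr(chroms[[cn]], s + 1L, e))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), seq = character(0))
  attr(out, "dropped") <- dropped
  out
}

#' Both-strand RNA of a DNA fragment
#'
#' The plus strand is the fragment with T converted to U; the minus strand
#' is the reverse complement, likewise converted.
#'
#' @param dna a DNA string (A/C/G/T/N).
#' @return list with `plus` and `minus` RNA strings.
#' @export
to_rna_both_strands <- function(dna) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("non-ACGTN character in DNA fragment")
  list(plus = chartr("T", "U", dna),
       minus = chartr("T", "U", revcomp_dna(dna)))
}

#' Extract hairpin elements from a folded fragment
#'
#' Finds every terminal loop of at least `min_loop_len` unpaired bases and
#' extends outward through the enclosing nested stem (across bulges and
#' internal loops) until the structure branches or ends; the element is kept
#' when its stem contains a run of at least `min_stem_run` consecutive
#' (stacked) base pairs. Offsets are 1-based positions within the folded
#' fragment.
#'
#' @param fold a `fold_result` (or list with `sequence` and `structure`).
#' @param min_stem_run minimum stacked-pair run (default 3).
#' @param min_loop_len minimum terminal-loop size (default 3).
#' @return data.frame `start`, `end`, `seq`, `struct` (zero rows when none).
#' @export
extract_hairpins <- function(fold, min_stem_run = 3L, min_loop_len = 3L) {
  struct <- fold$structure
  seq <- fold$sequence
  partner <- pair_partner(struct)
  L <- length(partner)
  bp <- parse_dotbracket(struct)
  rows <- list()
  if (nrow(bp)) for (r in seq_len(nrow(bp))) {
    i <- bp[r, "i"]; j <- bp[r, "j"]
    if (j - i - 1L < min_loop_len) next
    if (j - i - 1L > 0L && any(partner[(i + 1L):(j - 1L)] != 0L)) next
    # (i, j) closes a terminal loop; extend outward while uniquely enclosed
    a <- i; b <- j
    repeat {
      x <- a - 1L
      while (x >= 1L && partner[x] == 0L) x <- x - 1L
      y <- b + 1L
      while (y <= L && partner[y] == 0L) y <- y + 1L
      if (x >= 1L && y <= L && partner[x] == y) { a <- x; b <- y } else break
    }
    sub_struct <- substr(struct, a, b)
    sub_partner <- pair_partner(sub_struct)
    if (max(c(0L, .stack_runs(sub_partner))) < min_stem_run) next
    rows[[length(rows) + 1L]] <-
      data.frame(start = a, end = b, seq = substr(seq, a, b),
                 struct = sub_struct)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(start = integer(0), end = integer(0),
                  seq = character(0), struct = character(0))
}

#' Scan a genome for candidate pre-miRNA hairpins
#'
#' The full detection pipeline: fragment each chromosome into overlapping
#' windows, fold both strands, extract hairpin elements (stem with >= 3
#' stacked pairs, terminal loop >= 3 nt), filter by length, deduplicate
#' identical sequences genome-wide, and - when a fitted model is supplied -
#' compute features, score with every stored model, apply the ensemble
#' schemes and keep candidates whose averaged ensemble score reaches the
#' confidence threshold.
#'
#' @param chroms named character vector of DNA chromosomes (or a FASTA path).
#' @param fit optional `hairpin_mccv` model; `NULL` extracts candidates
#'   without scoring.
#' @param meta optional `consensus_model` for the ConsensusModel column.
#' @param window,step fragmentation geometry (defaults 500/250).
#' @param min_len,max_len hairpin length bounds (defaults 36/180).
#' @param threshold minimum averaged ensemble score (`avg_dt`) to report;
#'   ignored without `fit`.
#' @param controls optional numeric control scores; when given, `threshold`
#'   is derived from their lower quartile via [derive_threshold()].
#' @return data.frame of class `candidate_hairpins`: `chrom`, `start`,
#'   `end`, `strand` (0-based half-open genomic coordinates), `seq`,
#'   `struct`, `energy`, plus score/label columns when scored; a `summary`
#'   attribute carries pipeline counts.
#' @export
scan_genome <- function(chroms, fit = NULL, meta = NULL, window = 500L,
                        step = 250L, min_len = 36L, max_len = 180L,
                        threshold = 0, controls = NULL) {
  if (length(chroms) == 1L && is.null(names(chroms)) && file.exists(chroms))
    chroms <- read_fasta(chroms)
  if (!is.null(controls)) threshold <- derive_threshold(controls)
  frags <- fragment_genome(chroms, window, step, min_keep = min_len)
  cand <- list()
  for (f in seq_len(nrow(frags))) {
    strands <- to_rna_both_strands(frags$seq[f])
    flen <- nchar(frags$seq[f])
    for (strand in c("+", "-")) {
      rna <- if (strand == "+") strands$plus else strands$minus
      fr <- fold_rna(rna)
      hp <- extract_hairpins(fr)
      if (!nrow(hp)) next
      # map local 1-based [start, end] to genomic 0-based half-open
      gs <- if (strand == "+") frags$start[f] + hp$start - 1L
            else frags$start[f] + flen - hp$end
      ge <- if (strand == "+") frags$start[f] + hp$end
            else frags$start[f] + flen - hp$start + 1L
      cand[[length(cand) + 1L]] <-
        data.frame(chrom = frags$chrom[f], start = gs, end = ge,
                   strand = strand, seq = hp$seq, struct = hp$struct,
                   energy = -vapply(hp$struct,
                                    function(s) nrow(parse_dotbracket(s)),
                                    0L, USE.NAMES = FALSE))
    }
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), struct = character(0),
                      energy = numeric(0))
  cand <- if (length(cand)) do.call(rbind, cand) else empty
  n_extracted <- nrow(cand)
  L <- nchar(cand$seq)
  cand <- cand[L >= min_len & L <= max_len, , drop = FALSE]
  n_lenfilt <- nrow(cand)
  # genome-wide dedup: keep first candidate by (chrom, start, strand)
  cand <- cand[order(cand$chrom, cand$start, cand$strand), , drop = FALSE]
  dup_loci <- cand[duplicated(cand$seq), c("chrom", "start", "end", "strand"),
                   drop = FALSE]
  cand <- cand[!duplicated(cand$seq), , drop = FALSE]
  n_dedup <- nrow(cand)
  if (!is.null(fit) && nrow(cand)) {
    recs <- hairpin_records(cand$seq,
                            id = sprintf("cand_%s_%d_%d_%s", cand$chrom,
                                         cand$start, cand$end, cand$strand),
                            struct = cand$struct, energy = cand$energy,
                            source = "scan")
    miss <- setdiff(fit$feature_names, feature_registry("mfe")$name)
    if (length(miss))
      stop("model schema requires feature(s) the scan cannot compute: ",
           paste(miss, collapse = ", "))
    feats <- compute_features(recs)
    sc <- predict(fit, feats)
    ens <- ensemble_predict(sc, meta = meta)
    cand <- cbind(cand, ens[, setdiff(names(ens), "id"), drop = FALSE])
    cand <- cand[cand$avg_dt >= threshold, , drop = FALSE]
  }
  rownames(cand) <- NULL
  attr(cand, "summary") <- list(n_fragments = nrow(frags),
                                n_extracted = n_extracted,
                                n_length_filtered = n_lenfilt,
                                n_after_dedup = n_dedup,
                                n_reported = nrow(cand),
                                threshold = threshold,
                                duplicate_loci = dup_loci)
  class(cand) <- c("candidate_hairpins", "data.frame")
  cand
}
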