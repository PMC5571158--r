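#' Construct a hairpin record table
#'
#' The package-wide container for candidate hairpins: a plain data.frame
#' with columns `id`, `seq`, `struct`, `energy`, `label`, `rpm`, `source`.
#' Structure and energy are jointly present or jointly `NA` (fold on
#' demand); `label` is one of `"positive"`, `"negative"`, `"unlabeled"`.
#'
#' @param seq character vector of RNA/DNA sequences.
#' @param id record identifiers (default `hp_1`, `hp_2`, ...); must be unique.
#' @param struct optional dot-bracket structures.
#' @param energy optional folding energies (required with `struct`).
#' @param label record label.
#' @param rpm optional reads-per-million expression support.
#' @param source free-text provenance.
#' @return data.frame of class `hairpin_records`.
#' @export
hairpin_records <- function(seq, id = NULL, struct = NA_character_,
                            energy = NA_real_,
                            label = c("unlabeled", "positive", "negative"),
                            rpm = NA_real_, source = "user") {
  label <- match.arg(label)
  seq <- rna_sequence(seq)
  n <- length(seq)
  if (is.null(id)) id <- paste0("hp_", seq_len(n))
  if (anyDuplicated(id)) stop("record ids must be unique")
  if (any(xor(is.na(struct), is.na(energy))))
    stop("struct and energy must be jointly present or jointly absent")
  rec <- function(x) rep_len(x, n)
  df <- data.frame(id = as.character(id), seq = seq,
                   struct = rec(as.character(struct)),
                   energy = rec(as.numeric(energy)),
                   label = rec(label), rpm = rec(as.numeric(rpm)),
                   source = rec(source), stringsAsFactors = FALSE)
  class(df) <- c("hairpin_records", "data.frame")
  df
}

#' Fold any unfolded records in place
#' @param records hairpin records.
#' @param backend folding backend.
#' @return records with `struct`/`energy` filled.
#' @export
fold_records <- function(records, backend = "nussinov") {
  todo <- which(is.na(records$struct))
  for (r in todo) {
    fr <- fold_rna(records$seq[r], backend = backend)
    records$struct[r] <- fr$structure
    records$energy[r] <- fr$energy
  }
  records
}

#' Remove records with identical sequences
#'
#' Keeps the first occurrence (input order) of every distinct sequence
#' string, mirroring the redundancy filter applied to positive training
#' hairpins.
#'
#' @param records hairpin records.
#' @return deduplicated records.
#' @export
dedup_identical <- function(records) {
  records[!duplicated(records$seq), , drop = FALSE]
}

#' Filter hairpins by length
#'
#' Inclusive bounds; the defaults 36-180 nt are the span of human stem-loop
#' lengths observed in miRBase.
#'
#' @param records hairpin records.
#' @param min_len,max_len inclusive length bounds.
#' @return records whose sequence length lies in `[min_len, max_len]`.
#' @export
filter_by_length <- function(records, min_len = 36L, max_len = 180L) {
  if (min_len > max_len) stop("min_len exceeds max_len")
  L <- nchar(records$seq)
  records[L >= min_len & L <= max_len, , drop = FALSE]
}

#' Filter hairpins by expression support (RPM)
#'
#' @param records hairpin records carrying `rpm` metadata.
#' @param min_rpm minimum reads-per-million (kept iff `rpm >= min_rpm`).
#' @return filtered records.
#' @export
filter_by_rpm <- function(records, min_rpm = 100) {
  miss <- is.na(records$rpm)
  if (any(miss))
    stop("records missing rpm metadata: ",
         paste(records$id[miss], collapse = ", "))
  records[records$rpm >= min_rpm, , drop = FALSE]
}

# seeded evaluation that never disturbs the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Shuffled negative set
#'
#' Negative decoys built by permuting the residues of each input hairpin;
#' the nucleotide multiset of every sequence is preserved exactly. The
#' default is a uniform (Fisher-Yates) mononucleotide permutation; the
#' `"dinucleotide"` mode preserves dinucleotide composition via an
#' Altschul-Erikson-style shuffle restricted to a seeded random Eulerian
#' ordering of the transition multigraph.
#'
#' @param records hairpin records.
#' @param seed integer seed; the construction is deterministic given it.
#' @param mode `"mono"` (default) or `"dinucleotide"`.
#' @return hairpin records labeled negative, ids suffixed `_shuf`, with a
#'   `provenance` attribute recording operation, parameters and seed.
#' @export
make_shuffled <- function(records, seed, mode = c("mono", "dinucleotide")) {
  mode <- match.arg(mode)
  out <- .with_seed(seed, {
    shuf <- vapply(records$seq, function(x) {
      s <- strsplit(x, "")[[1]]
      if (mode == "mono") paste(sample(s), collapse = "")
      else .dinuc_shuffle(s)
    }, "", USE.NAMES = FALSE)
    hairpin_records(shuf, id = paste0(records$id, "_shuf"),
                    label = "negative", source = "make_shuffled")
  })
  attr(out, "provenance") <- list(operation = "make_shuffled", seed = seed,
                                  mode = mode, n = nrow(records))
  out
}

# dinucleotide-preserving shuffle: random walk over the residue transition
# graph consuming each observed transition exactly once, retried until the
# walk covers all transitions (inputs here are short, retries are cheap)
.dinuc_shuffle <- function(s) {
  L <- length(s)
  if (L < 3L) return(paste(s, collapse = ""))
  edges <- split(s[-1L], s[-L])
  for (try in 1:200) {
    pool <- lapply(edges, sample)
    walk <- character(L); walk[1L] <- s[1L]
    ok <- TRUE
    for (k in 2:L) {
      from <- walk[k - 1L]
      nxt <- pool[[from]]
      if (is.null(nxt) || !length(nxt)) { ok <- FALSE; break }
      walk[k] <- nxt[1L]
      pool[[from]] <- nxt[-1L]
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  paste(s, collapse = "") # degenerate composition: return input unchanged
}

#' Suboptimal-fold negative set
#'
#' Negative decoys sharing the exact sequences of the (positive) inputs but
#' paired with a suboptimal secondary structure instead of the optimal fold.
#' Records whose sequence admits no alternative structure are skipped and
#' listed in the `skipped` attribute.
#'
#' @param records hairpin records.
#' @param backend folding backend.
#' @return hairpin records labeled negative with suboptimal `struct`/`energy`.
#' @export
make_notbestfold <- function(records, backend = "nussinov") {
  keep <- logical(nrow(records))
  structs <- character(nrow(records))
  energies <- numeric(nrow(records))
  for (r in seq_len(nrow(records))) {
    alt <- subopt_fold(records$seq[r], k = 1L, backend = backend)
    if (length(alt)) {
      keep[r] <- TRUE
      structs[r] <- alt[[1]]$structure
      energies[r] <- alt[[1]]$energy
    }
  }
  out <- hairpin_records(records$seq[keep],
                         id = paste0(records$id[keep], "_nbf"),
                         struct = structs[keep], energy = energies[keep],
                         label = "negative", source = "make_notbestfold")
  attr(out, "provenance") <- list(operation = "make_notbestfold",
                                  backend = backend, n_in = nrow(records),
                                  n_out = nrow(out))
  attr(out, "skipped") <- records$id[!keep]
  out
}

#' Feature-space synthetic data sets (FR / BQ / AM)
#'
#' Builds a synthetic feature matrix by drawing each feature independently
#' and uniformly within a per-feature interval estimated from a reference
#' matrix: full range min..max (`"FR"`), lower..upper quartile (`"BQ"`), or
#' 40th..60th percentile (`"AM"`). Quantiles use linear interpolation
#' between order statistics (type 7). The interval nesting AM within BQ
#' within FR holds per feature by construction.
#'
#' @param mat numeric feature matrix (rows = hairpins).
#' @param mode `"FR"`, `"BQ"` or `"AM"`.
#' @param n number of synthetic rows (default 5000).
#' @param seed integer seed.
#' @return numeric matrix `n` x `ncol(mat)` with a `provenance` attribute.
#' @export
make_feature_space_set <- function(mat, mode = c("FR", "BQ", "AM"),
                                   n = 5000L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(dim(mat)) || nrow(mat) == 0L) stop("empty feature matrix")
  probs <- switch(mode, FR = c(0, 1), BQ = c(0.25, 0.75), AM = c(0.40, 0.60))
  lo <- apply(mat, 2L, stats::quantile, probs = probs[1], type = 7, names = FALSE)
  hi <- apply(mat, 2L, stats::quantile, probs = probs[2], type = 7, names = FALSE)
  out <- .with_seed(seed, {
    m <- vapply(seq_along(lo),
                function(j) stats::runif(n, lo[j], hi[j]),
                numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    m
  })
  dimnames(out) <- list(paste0(tolower(mode), "_", seq_len(n)), colnames(mat))
  attr(out, "provenance") <- list(operation = "make_feature_space_set",
                                  mode = mode, n = n, seed = seed,
                                  lo = lo, hi = hi)
  out
}
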