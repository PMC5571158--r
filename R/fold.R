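#' @useDynLib premirna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.allowed_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

.min_loop <- 3L

#' Predict the secondary structure of an RNA sequence
#'
#' Two backends are available. `"nussinov"` (default, always available) is a
#' self-contained maximum base-pairing dynamic program over Watson-Crick and
#' G-U wobble pairs with a minimum terminal loop of 3 nt; its "energy" is the
#' surrogate score -(number of base pairs) and is flagged as such. `"vienna"`
#' shells out to the RNAfold binary when it is on the PATH and returns the
#' thermodynamic minimum free energy (MFE) structure in kcal/mol.
#'
#' @param seq a single RNA (or DNA, converted) sequence.
#' @param backend `"nussinov"` or `"vienna"`.
#' @return a `fold_result` list: `sequence`, `structure`, `energy`,
#'   `backend_id`, `is_mfe`, `energy_is_surrogate`.
#' @examples
#' fold_rna("GGGAAACCC")$structure  # "(((...)))"
#' @export
fold_rna <- function(seq, backend = c("nussinov", "vienna")) {
  backend <- match.arg(backend)
  seq <- rna_sequence(seq)
  stopifnot(length(seq) == 1L)
  if (backend == "vienna") {
    return(.fold_vienna(seq))
  }
  res <- .nussinov_fold(seq)
  structure(list(sequence = seq,
                 structure = res$structure,
                 energy = -as.numeric(res$n_pairs),
                 backend_id = "nussinov",
                 is_mfe = TRUE,
                 energy_is_surrogate = TRUE),
            class = "fold_result")
}

.fold_vienna <- function(seq) {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin))
    stop("RNAfold binary not found on PATH; use backend = \"nussinov\" ",
         "(self-contained fallback)")
  out <- system2(bin, c("--noPS"), input = seq, stdout = TRUE)
  line <- out[2L]
  m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stop("could not parse RNAfold output: ", line)
  structure(list(sequence = seq,
                 structure = m[2L],
                 energy = as.numeric(m[3L]),
                 backend_id = paste0("vienna-RNAfold"),
                 is_mfe = TRUE,
                 energy_is_surrogate = FALSE),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$energy), ")",
      if (x$energy_is_surrogate) " [surrogate energy]", "\n", sep = "")
  invisible(x)
}

#' Suboptimal secondary structures
#'
#' Returns up to `k` valid structures distinct from (and strictly worse than
#' or equal in pair count to) the optimal structure, best first. Under the
#' Nussinov backend each suboptimal is obtained by re-running the dynamic
#' program with one of the optimal structure's base pairs forbidden; the
#' resulting structures are deduplicated and ordered by surrogate energy.
#' Sequences admitting no alternative structure yield an empty list.
#'
#' @param seq RNA sequence.
#' @param k maximum number of suboptimal structures (k = 0 gives `list()`).
#' @param backend folding backend (see [fold_rna()]).
#' @return list of `fold_result` objects with `is_mfe = FALSE`.
#' @export
subopt_fold <- function(seq, k = 1L, backend = c("nussinov", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(k >= 0)
  if (k == 0) return(list())
  if (backend == "vienna") return(.subopt_vienna(seq, k))
  mfe <- fold_rna(seq, backend = "nussinov")
  bp <- parse_dotbracket(mfe$structure)
  if (!nrow(bp)) return(list())
  alts <- list()
  for (r in seq_len(nrow(bp))) {
    res <- .nussinov_fold(mfe$sequence, bp[r, "i"], bp[r, "j"])
    if (res$structure == mfe$structure) next # cannot happen, defensive
    alts[[res$structure]] <- res$n_pairs
  }
  if (!length(alts)) return(list())
  db <- names(alts)
  np <- unlist(alts, use.names = FALSE)
  ord <- order(-np, db) # best surrogate energy first, then lexicographic
  db <- db[ord]; np <- np[ord]
  n_take <- min(k, length(db))
  lapply(seq_len(n_take), function(t)
    structure(list(sequence = mfe$sequence, structure = db[t],
                   energy = -as.numeric(np[t]), backend_id = "nussinov",
                   is_mfe = FALSE, energy_is_surrogate = TRUE),
              class = "fold_result"))
}

# RNAsubopt delegation for the thermodynamic backend: native sorted
# suboptimal enumeration within 2 kcal/mol of the MFE.
.subopt_vienna <- function(seq, k) {
  bin <- Sys.which("RNAsubopt")
  if (!nzchar(bin))
    stop("RNAsubopt binary not found on PATH; use backend = \"nussinov\"")
  seq <- rna_sequence(seq)
  mfe <- .fold_vienna(seq)
  out <- system2(bin, c("--sorted", "-e", "2"), input = seq, stdout = TRUE)
  out <- out[-1L] # header line echoes the sequence
  db <- sub("\\s.*$", "", out)
  en <- as.numeric(sub("^\\S+\\s+", "", out))
  keep <- db != mfe$structure & !duplicated(db)
  db <- db[keep][seq_len(min(k, sum(keep)))]
  en <- en[keep][seq_len(min(k, sum(keep)))]
  lapply(seq_along(db), function(t)
    structure(list(sequence = seq, structure = db[t], energy = en[t],
                   backend_id = "vienna-RNAsubopt", is_mfe = FALSE,
                   energy_is_surrogate = FALSE),
              class = "fold_result"))
}

#' Exhaustively enumerate all valid secondary structures
#'
#' Brute-force enumeration of every nested structure with terminal loops of
#' at least 3 nt over Watson-Crick plus G-U pairs. Intended as a testing
#' oracle for the dynamic-programming folder; guarded to short sequences.
#'
#' @param seq RNA sequence of length at most `max_len`.
#' @param max_len combinatorial guard (default 14).
#' @return character vector of dot-bracket structures (includes the
#'   all-unpaired structure), duplicate-free.
#' @export
enumerate_structures <- function(seq, max_len = 14L) {
  seq <- rna_sequence(seq)
  n <- nchar(seq)
  if (n > max_len)
    stop("sequence length ", n, " exceeds enumeration guard (", max_len, ")")
  s <- strsplit(seq, "")[[1]]
  pairable <- function(a, b) paste0(a, b) %in% .allowed_pairs
  rec <- function(i, j) {
    if (i > j) return("")
    out <- paste0(".", rec(i + 1L, j))
    if (j - i > .min_loop) {
      for (kk in seq.int(i + .min_loop + 1L, j)) {
        if (!pairable(s[i], s[kk])) next
        inner <- rec(i + 1L, kk - 1L)
        after <- rec(kk + 1L, j)
        out <- c(out, as.vector(outer(inner, after,
                                      function(a, b) paste0("(", a, ")", b))))
      }
    }
    unique(out)
  }
  rec(1L, n)
}
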