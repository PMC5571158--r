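#' Normalize a nucleotide string to canonical RNA
#'
#' Uppercases, converts DNA thymine to uracil, and validates the alphabet.
#' Ambiguity codes (N and friends) are rejected by default because silently
#' coercing them would corrupt downstream feature values; `ambig = "map_a"`
#' maps every IUPAC ambiguity code to A with a warning.
#'
#' @param x character vector of nucleotide strings (DNA or RNA).
#' @param ambig `"error"` (default) or `"map_a"`.
#' @return character vector over the alphabet A, C, G, U.
#' @examples
#' rna_sequence("acgt")   # "ACGU"
#' @export
rna_sequence <- function(x, ambig = c("error", "map_a")) {
  ambig <- match.arg(ambig)
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  if (any(!nzchar(x))) stop("empty sequence")
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    if (ambig == "error") {
      ch <- unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), "")))
      stop("non-ACGU characters in sequence: ", paste(ch, collapse = ", "),
           " (use ambig = \"map_a\" to map ambiguity codes to A)")
    }
    warning("mapping ambiguity codes to A in ", sum(bad), " sequence(s)")
    x <- gsub("[^ACGU]", "A", x)
  }
  x
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return reverse-complemented DNA, same case as input uppercased.
#' @export
revcomp_dna <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Parse a dot-bracket secondary structure into base pairs
#'
#' @param structure a dot-bracket string over `(`, `)` and `.`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`), one row
#'   per base pair; zero rows for an unpaired structure.
#' @examples
#' parse_dotbracket("(((...)))")
#' @export
parse_dotbracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  ch <- strsplit(structure, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid structure character '", ch[bad[1]], "' at position ", bad[1])
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  ii <- integer(length(ch)); jj <- integer(length(ch)); np <- 0L
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack))
        stop("unbalanced structure: unmatched ')' at position ", k)
      np <- np + 1L
      ii[np] <- stack[length(stack)]; jj[np] <- k
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ", stack[1])
  if (np) out <- cbind(i = ii[seq_len(np)], j = jj[seq_len(np)])
  out[order(out[, 1L]), , drop = FALSE]
}

#' Partner vector of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; `p[k]` is the 1-based partner of position `k`,
#'   or 0 when unpaired.
#' @keywords internal
pair_partner <- function(structure) {
  bp <- parse_dotbracket(structure)
  p <- integer(nchar(structure))
  if (nrow(bp)) {
    p[bp[, "i"]] <- bp[, "j"]
    p[bp[, "j"]] <- bp[, "i"]
  }
  p
}
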