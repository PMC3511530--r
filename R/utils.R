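# Small sequence utilities shared across modules. Sequences are plain
# upper-case character scalars over {A,C,G,T,N}; Biostrings objects are used
# only at file-format boundaries.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over `A,C,G,T,N` (case-insensitive).
#' @return Upper-case reverse-complemented character scalar.
#' @examples
#' revcomp("CGTTCCA")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- check_dna(seq)
  paste(rev(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Validate and upper-case a DNA scalar; U and other letters are rejected.
check_dna <- function(seq, allow_n = TRUE) {
  x <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), strsplit(alphabet, "")[[1]])
  if (length(bad) > 0) {
    abort(sprintf("invalid DNA character(s): %s", paste(bad, collapse = ", ")))
  }
  x
}

# Random DNA scalar with the given GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Replace bases of `seq` at 1-based positions pos..pos+nchar(insert)-1.
splice_seq <- function(seq, pos, insert) {
  stopifnot(pos >= 1, pos + nchar(insert) - 1 <= nchar(seq))
  paste0(
    substr(seq, 1, pos - 1), insert,
    substr(seq, pos + nchar(insert), nchar(seq))
  )
}

# Minimal IUPAC code covering a set of observed bases (subset of ACGT).
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  "N"
}
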