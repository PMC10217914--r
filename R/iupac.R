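# IUPAC nucleotide machinery shared by every module. Sequences are plain
# uppercase character strings over {A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N,-}.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# base-set (sorted, collapsed) -> minimal covering code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(keys), keys)
})

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

# match_matrix[code, base]: TRUE iff a primer position with `code` pairs with
# a template base `base` (template read on the same strand as the primer).
# Template "N" matches nothing unless the permissive-N flag is on; "-" never.
IUPAC_MATCH <- local({
  tmpl <- c("A", "C", "G", "T", "N", "-")
  m <- matrix(FALSE, length(IUPAC_CODES), length(tmpl),
              dimnames = list(IUPAC_CODES, tmpl))
  for (code in IUPAC_CODES) m[code, IUPAC_SETS[[code]]] <- TRUE
  m
})

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

assert_iupac <- function(seq, allow_gap = FALSE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single string.", what))
  }
  if (!nzchar(seq)) abort(sprintf("`%s` must not be empty.", what))
  ok <- c(IUPAC_CODES, if (allow_gap) "-")
  ch <- seq_chars(seq)
  bad <- which(!ch %in% ok)
  if (length(bad)) {
    abort(sprintf("invalid character '%s' at position %d of %s",
                  ch[bad[1]], bad[1], what))
  }
  invisible(seq)
}

normalize_seq <- function(seq) {
  chartr("uU", "TT", toupper(seq))
}

#' Expand a degenerate IUPAC sequence into concrete sequences
#'
#' Every IUPAC ambiguity code is expanded to the set of A/C/G/T bases it
#' covers; the result is the cartesian product over positions, sorted
#' lexicographically. `"AAGCCTYCTYATTCGTGC"` (two Y codes) expands to 4
#' concrete primers.
#'
#' @param seq A single IUPAC string (no gaps).
#' @param max_expansions Error if the expansion count exceeds this.
#' @return Character vector of concrete A/C/G/T sequences, sorted.
#' @export
#' @examples
#' expand_degenerate("ACYG")
expand_degenerate <- function(seq, max_expansions = 4096) {
  seq <- normalize_seq(seq)
  assert_iupac(seq)
  sets <- IUPAC_SETS[seq_chars(seq)]
  n <- prod(lengths(sets))
  if (n > max_expansions) {
    abort(sprintf("sequence expands to %d > %d concrete sequences",
                  n, max_expansions))
  }
  out <- Reduce(function(acc, s) {
    as.vector(vapply(s, function(b) paste0(acc, b),
                     character(length(acc))))
  }, sets, accumulate = FALSE, init = "")
  sort(out)
}

degeneracy_of <- function(seq) {
  prod(lengths(IUPAC_SETS[seq_chars(seq)]))
}

#' GC content of an IUPAC sequence
#'
#' Ambiguity codes contribute their expected G+C fraction (S counts 1,
#' W counts 0, R/Y/N count 0.5, B counts 2/3, ...).
#'
#' @param seq A single IUPAC string (no gaps).
#' @return GC fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("TTCGGGGGAAAGCCATATCG") # 0.55
gc_content <- function(seq) {
  seq <- normalize_seq(seq)
  assert_iupac(seq)
  fr <- vapply(IUPAC_SETS[seq_chars(seq)],
               function(b) mean(b %in% c("G", "C")), 0)
  mean(fr)
}

#' Reverse complement of an IUPAC sequence
#'
#' Each code maps to its complement code (Y -> R, S -> S, ...); gaps are
#' preserved.
#'
#' @param seq A single IUPAC string.
#' @return The reverse complement, same alphabet.
#' @export
#' @examples
#' reverse_complement("ACYG") # "CRGT"
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  assert_iupac(seq, allow_gap = TRUE)
  paste(rev(IUPAC_COMPLEMENT[seq_chars(seq)]), collapse = "")
}

# Minimal IUPAC code covering a set of observed concrete bases.
# Input may itself contain ambiguity codes; they are expanded first.
iupac_union_code <- function(bases) {
  expanded <- unique(unlist(IUPAC_SETS[bases], use.names = FALSE))
  IUPAC_FROM_SET[[paste(sort(expanded), collapse = "")]]
}

max_homopolymer_run <- function(seq) {
  r <- rle(seq_chars(seq))
  max(r$lengths)
}
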