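# internal helpers shared across modules

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# IUPAC nucleotide codes -> set of concrete bases each matches.
# Ambiguous bases in the *genome* never satisfy a pattern position
# (fail-closed), so the values contain concrete bases only.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# reverse complement of a plain character string (ACGTN etc.)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# variant key used for exact-match set operations
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
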