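# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement on plain character strings (A/C/G/T/N).
#' Empty strings are returned unchanged, which lets the sequence-feature code
#' treat the empty allele of a pure insertion or deletion uniformly.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Stable variant identity key
#'
#' Builds the canonical `chrom:pos:ref:alt` key used to join variants against
#' external score tables. Empty alleles (decomposed insertion/deletion parts)
#' are encoded as `-` so the key never contains an empty field.
#'
#' @param chrom,pos,ref,alt vectors describing normalised variants.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos,
        ifelse(!nzchar(ref), "-", ref),
        ifelse(!nzchar(alt), "-", alt), sep = ":")
}

# Deterministic 31-polynomial rolling hash (mod 2^31 - 1), hex-formatted.
# Used to fingerprint feature registries and run configurations; not
# cryptographic, just a stable identity check.
st_hash <- function(x) {
  x <- paste(x, collapse = "\x1f")
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Format numbers for text outputs (VCF INFO, TSV mirrors) in a single
# canonical way so that re-reading a written file reproduces the values
# bit-exactly as formatted.
fmt_num <- function(x, missing = ".") {
  out <- ifelse(is.na(x), missing, sprintf("%.6g", as.numeric(x)))
  out
}

fmt_bool <- function(x, missing = ".") {
  ifelse(is.na(x), missing, ifelse(as.logical(x), "1", "0"))
}

# Truncated (clipped) normal draw used by the score simulator.
rnorm_clip <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}
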