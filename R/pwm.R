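# Position-weight-matrix scoring of exonic splicing enhancer/silencer
# motifs, and the per-variant delta scores fed to the consensus model.

#' Read a PWM set file
#'
#' The file format is plain text: for each matrix a header line
#' `NAME WIDTH ROLE THRESHOLD` (role `enhancer` or `silencer`) followed by
#' WIDTH rows of four whitespace-separated reals in A C G T order. Blank
#' lines and `#` comments are ignored. Weights follow the log-odds
#' convention: a window score is the sum of per-position weights.
#'
#' @param path PWM set file.
#' @return named list of `pwm` objects (`name`, `width`, `role`,
#'   `threshold`, `mat` a width x 4 matrix with columns A,C,G,T).
#' @export
read_pwm_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(hdr) != 4L)
      stop("bad PWM header at block starting '", lines[i], "'")
    width <- as.integer(hdr[2L])
    if (is.na(width) || width < 1L) stop("bad PWM width for ", hdr[1L])
    role <- match.arg(hdr[3L], c("enhancer", "silencer"))
    if (i + width > length(lines)) stop("truncated PWM block for ", hdr[1L])
    mat <- t(vapply(lines[(i + 1L):(i + width)], function(l) {
      vals <- suppressWarnings(as.numeric(strsplit(l, "[ \t]+")[[1]]))
      if (length(vals) != 4L || anyNA(vals))
        stop("bad PWM weight row for ", hdr[1L], ": '", l, "'")
      vals
    }, numeric(4), USE.NAMES = FALSE))
    colnames(mat) <- c("A", "C", "G", "T")
    if (hdr[1L] %in% names(pwms)) stop("duplicate PWM name: ", hdr[1L])
    pwms[[hdr[1L]]] <- structure(
      list(name = hdr[1L], width = width, role = role,
           threshold = as.numeric(hdr[4L]), mat = mat),
      class = "pwm")
    i <- i + width + 1L
  }
  pwms
}

#' Default ESE/ESS PWM set
#'
#' Loads the PWM set shipped with the package: consensus-derived synthetic
#' stand-ins for the five SR-protein exonic splicing enhancer motifs
#' (SRSF1, SRSF1 igM-BRCA2 variant, SRSF2, SRSF5, SRSF6) and the hnRNP A1
#' exonic splicing silencer, in the documented text format. The matrices
#' are editable data files; drop-in replacement with experimentally derived
#' matrices (e.g. the ESEFinder SELEX matrices) is supported and the
#' published ESEFinder score thresholds are kept as the defaults.
#'
#' @return named list of `pwm` objects.
#' @export
default_pwms <- function() {
  read_pwm_set(system.file("extdata", "pwm_synthetic_ese_ess.txt",
                           package = "splicetree", mustWork = TRUE))
}

#' Best PWM window score of a sequence
#'
#' Scans every width-length window of `seq` and returns the maximum sum of
#' per-position weights. Bases outside A/C/G/T contribute weight 0.
#'
#' @param seq nucleotide string, at least `pwm$width` long.
#' @param pwm a `pwm` object.
#' @return best window score (numeric scalar).
#' @export
score_pwm_window <- function(seq, pwm) {
  s <- toupper(seq)
  n <- nchar(s)
  w <- pwm$width
  if (n < w) stop("sequence shorter than PWM width (", n, " < ", w, ")")
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  best <- -Inf
  for (i in seq_len(n - w + 1L)) {
    wi <- pwm$mat[cbind(seq_len(w), idx[i:(i + w - 1L)])]
    wi[is.na(wi)] <- 0
    sc <- sum(wi)
    if (sc > best) best <- sc
  }
  best
}

#' PWM delta between two haplotype contexts
#'
#' `best_score(alt_context) - best_score(ref_context)`, each taken over all
#' windows of the provided context. Callers provide contexts that span the
#' changed bases plus `width - 1` flanking bases on each side, so the delta
#' covers exactly the windows overlapping the change. Returns `NA` when
#' either context is shorter than the motif (contig-edge truncation).
#'
#' @param ref_context,alt_context nucleotide strings.
#' @param pwm a `pwm` object.
#' @return numeric delta, or `NA_real_` if a context cannot be scored.
#' @export
delta_pwm <- function(ref_context, alt_context, pwm) {
  if (nchar(ref_context) < pwm$width || nchar(alt_context) < pwm$width)
    return(NA_real_)
  score_pwm_window(alt_context, pwm) - score_pwm_window(ref_context, pwm)
}

# Extract the ref/alt haplotype windows around a variant's changed bases
# with `flank` bases on each side; clipped at the contig edges.
variant_windows <- function(chromseq, v, flank) {
  core <- variant_core(v)
  len <- nchar(chromseq)
  a <- core$start - flank
  b <- core$start + max(nchar(core$ref), 1L) - 1L + flank
  if (nchar(core$ref) == 0L) b <- core$start - 1L + flank # pure insertion
  truncated <- a < 1L || b > len
  a <- max(a, 1L); b <- min(b, len)
  ref_win <- substr(chromseq, a, b)
  alt_win <- paste0(substr(chromseq, a, core$start - 1L), core$alt,
                    substr(chromseq, core$start + nchar(core$ref), b))
  list(ref = ref_win, alt = alt_win, truncated = truncated)
}

#' PWM delta of a variant against the reference sequence
#'
#' Builds the reference and alternate contexts around the variant's changed
#' bases (motif width minus one flanking bases each side), reverse-
#' complements them for minus-strand transcripts, and returns the best-
#' window score difference.
#'
#' @param v single-row variant data.frame.
#' @param chromseq reference chromosome sequence (character scalar).
#' @param pwm a `pwm` object.
#' @param strand transcript strand, `"+"` or `"-"`.
#' @return numeric delta (`NA` when the context is shorter than the motif).
#' @export
pwm_delta_variant <- function(v, chromseq, pwm, strand = "+") {
  win <- variant_windows(chromseq, v, pwm$width - 1L)
  ref <- win$ref; alt <- win$alt
  if (strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  delta_pwm(ref, alt, pwm)
}
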