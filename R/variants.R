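# VCF reading, allele normalisation, region/allele-frequency filters and
# complex-variant decomposition.
#
# Variants live in an ordinary data frame with columns chrom, pos (1-based),
# ref, alt, vclass, af_popmax and id. Pure insertions and deletions keep the
# VCF anchor base; MNV and insdel alleles are fully trimmed (no shared
# prefix/suffix), so decomposition never has to guess an anchor.

#' Allele-frequency filter configuration
#'
#' @param af_max maximum population (popmax-style) allele frequency retained
#'   (default 0.01).
#' @param missing_af_passes should variants absent from the population
#'   database pass the filter (default TRUE: absence implies rarity)?
#' @return object of class `filter_config`.
#' @export
filter_config <- function(af_max = 0.01, missing_af_passes = TRUE) {
  if (is.na(af_max) || af_max < 0 || af_max > 1)
    stop("af_max must be in [0, 1]")
  structure(list(af_max = af_max,
                 missing_af_passes = isTRUE(missing_af_passes)),
            class = "filter_config")
}

# Parsimony trimming: drop shared suffix then shared prefix, always keeping
# at least one base of each allele; the position advances with the prefix.
normalize_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a normalised allele pair
#'
#' @param ref,alt normalised allele strings (possibly empty for internal
#'   decomposition parts).
#' @return one of `"SNV"`, `"insertion"`, `"deletion"`, `"MNV"`, `"insdel"`.
#' @export
variant_class <- function(ref, alt) {
  if (ref == alt) stop("ref and alt alleles are identical")
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 0L) return("insertion")
  if (na == 0L) return("deletion")
  if (nr == 1L && na == 1L) return("SNV")
  if (nr == na) return("MNV")
  if (na > nr && substr(alt, 1L, nr) == ref) return("insertion")
  if (nr > na && substr(ref, 1L, na) == alt) return("deletion")
  "insdel"
}

# The "core" of a variant: first changed reference base (1-based) and the
# changed allele substrings with any anchor base removed. For a pure
# insertion the core ref is empty and `start` is the position the alt bases
# are inserted before.
variant_core <- function(v) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  anchored <- nchar(ref) >= 1L && nchar(alt) >= 1L && nchar(ref) != nchar(alt) &&
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  if (anchored) {
    list(start = pos + 1L, ref = substr(ref, 2L, nchar(ref)),
         alt = substr(alt, 2L, nchar(alt)))
  } else {
    list(start = pos, ref = ref, alt = alt)
  }
}

parse_info_field <- function(info, keys) {
  for (key in keys) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2L) return(suppressWarnings(as.numeric(m[2L])))
  }
  NA_real_
}

#' Read a VCF of small variants
#'
#' Multi-allelic records are split into one variant per alt allele; shared
#' ref/alt prefixes and suffixes are trimmed (parsimony normalisation, the
#' position shifting with the prefix). Symbolic, spanning-deletion and
#' non-ACGT alleles are dropped with a warning. A popmax-style allele
#' frequency is parsed from the INFO keys `gnomAD_PopMax_AF`, `AF_POPMAX`
#' or `AF_popmax` when present.
#'
#' @param path VCF v4.x file (site-level; genotypes ignored).
#' @return data.frame with columns chrom, pos, ref, alt, vclass, af_popmax,
#'   id, in input order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "#CHROM")))
    stop("missing #CHROM header line in ", path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 8L))
    stop("malformed VCF record at line ", body[which(nf < 8L)[1L]],
         ": fewer than 8 fields")
  if (!length(body)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vclass = character(0), af_popmax = numeric(0),
                      id = character(0), stringsAsFactors = FALSE))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  out <- vector("list", nrow(fix))
  dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    af <- parse_info_field(fix[i, "INFO"] %||% ".",
                           c("gnomAD_PopMax_AF", "AF_POPMAX", "AF_popmax"))
    rows <- list()
    for (alt in alts) {
      if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt) || ref == alt) {
        dropped <- dropped + 1L
        next
      }
      nm <- normalize_allele(as.integer(fix[i, "POS"]), ref, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = nm$pos, ref = nm$ref, alt = nm$alt,
        vclass = variant_class(nm$ref, nm$alt), af_popmax = af,
        id = variant_key(fix[i, "CHROM"], nm$pos, nm$ref, nm$alt),
        stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (dropped > 0L)
    warning(dropped, " allele(s) dropped (symbolic, N-containing or ref==alt)")
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vclass = character(0), af_popmax = numeric(0),
                      id = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset variants to those overlapping gene models
#'
#' Retains variants whose reference span intersects the span of any retained
#' gene and annotates the overlapping gene id(s) (comma-separated).
#'
#' @param variants data.frame from [read_vcf()].
#' @param models gene models from [load_gene_models()].
#' @return filtered data.frame with an added `gene_ids` column.
#' @export
filter_by_regions <- function(variants, models) {
  if (!length(models) || !nrow(variants)) {
    variants$gene_ids <- character(nrow(variants))
    return(variants[integer(0), , drop = FALSE])
  }
  spans <- do.call(rbind, lapply(models, function(m) {
    sp <- gene_span(m)
    data.frame(chrom = m$chrom, start = sp["start"] + 1L, end = sp["end"],
               gene_id = m$gene_id, stringsAsFactors = FALSE)
  }))
  gr_genes <- GenomicRanges::GRanges(spans$chrom,
                                     IRanges::IRanges(spans$start, spans$end))
  width <- pmax(nchar(variants$ref), 1L)
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos + width - 1L))
  ov <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  keep <- sort(unique(S4Vectors::queryHits(ov)))
  gene_ids <- vapply(keep, function(q) {
    paste(spans$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == q]],
          collapse = ",")
  }, character(1))
  res <- variants[keep, , drop = FALSE]
  res$gene_ids <- gene_ids
  rownames(res) <- NULL
  res
}

#' Filter variants on population allele frequency
#'
#' Retains variants with `af_popmax <= af_max`; variants with a missing
#' frequency pass when `missing_af_passes` is set (the default).
#'
#' @param variants variant data.frame.
#' @param cfg a [filter_config()].
#' @return filtered data.frame.
#' @export
filter_by_af <- function(variants, cfg = filter_config()) {
  keep <- ifelse(is.na(variants$af_popmax), cfg$missing_af_passes,
                 variants$af_popmax <= cfg$af_max)
  res <- variants[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Decompose a complex variant into deletion and insertion parts
#'
#' MNV and insdel variants are split into a pure deletion of the reference
#' allele and a pure insertion of the alternate allele at the same locus, so
#' external predictors that cannot score complex variants can score the
#' parts (their per-category scores are then combined with the max rule).
#' SNVs, insertions and deletions are returned unchanged as a single part.
#'
#' @param v single-row variant data.frame.
#' @return data.frame of parts (1 or 2 rows); part alleles are unanchored
#'   and empty alleles appear as `-` in the id key.
#' @export
decompose_complex <- function(v) {
  if (nrow(v) != 1L) stop("decompose_complex expects a single variant")
  if (!v$vclass %in% c("MNV", "insdel")) {
    return(v[, c("chrom", "pos", "ref", "alt", "vclass", "id"), drop = FALSE])
  }
  parts <- data.frame(
    chrom = v$chrom, pos = v$pos,
    ref = c(v$ref, ""), alt = c("", v$alt),
    vclass = c("deletion", "insertion"),
    stringsAsFactors = FALSE)
  parts$id <- variant_key(parts$chrom, parts$pos, parts$ref, parts$alt)
  parts
}
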