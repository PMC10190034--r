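# Gene models, intron derivation and splice-region classification.
#
# Internal coordinates are 0-based half-open throughout; 1-based genomic
# positions (the VCF convention) are converted at the function boundary.

#' Splice-region window configuration
#'
#' Defines the donor and acceptor windows used for region classification:
#' the donor site spans the last `donor_exonic_nt` bases of an exon plus the
#' first `donor_intronic_nt` bases of the following intron (transcript
#' 5'->3' sense); the acceptor spans the first `acceptor_exonic_nt` bases of
#' an exon plus the last `acceptor_intronic_nt` bases of the preceding
#' intron. Defaults are donor 3+6 and acceptor 3+12 nt.
#'
#' @param donor_exonic_nt,donor_intronic_nt,acceptor_exonic_nt,acceptor_intronic_nt
#'   non-negative window widths in nucleotides.
#' @return object of class `region_config`.
#' @export
region_config <- function(donor_exonic_nt = 3L, donor_intronic_nt = 6L,
                          acceptor_exonic_nt = 3L, acceptor_intronic_nt = 12L) {
  vals <- c(donor_exonic_nt, donor_intronic_nt,
            acceptor_exonic_nt, acceptor_intronic_nt)
  if (any(is.na(vals)) || any(vals < 0))
    stop("region window widths must be non-negative")
  structure(list(donor_exonic_nt = as.integer(donor_exonic_nt),
                 donor_intronic_nt = as.integer(donor_intronic_nt),
                 acceptor_exonic_nt = as.integer(acceptor_exonic_nt),
                 acceptor_intronic_nt = as.integer(acceptor_intronic_nt)),
            class = "region_config")
}

new_gene_model <- function(gene_id, chrom, strand, biotype, transcripts,
                           structure_known = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  for (tx in transcripts) {
    ex <- tx$exons
    if (nrow(ex) < 1L) stop("transcript without exons: ", tx$transcript_id)
    if (is.unsorted(ex[, 1L])) stop("exons must be sorted")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("overlapping exons in transcript ", tx$transcript_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 biotype = biotype, transcripts = transcripts,
                 structure_known = structure_known),
            class = "gene_model")
}

# Quick line-oriented sanity scan so format errors can name the offending
# line; rtracklayer's parser does the real work afterwards.
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf < 9L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], ": expected 9 tab-separated fields")
  invisible(TRUE)
}

#' Load gene models from GTF or BED
#'
#' GTF input (Ensembl/GENCODE attribute dialect) yields full transcript/exon
#' structure; introns are derived as the gaps between consecutive exons. BED
#' input carries no transcript structure, so each interval becomes a single
#' "exon" region record usable only for subsetting (`structure_known` is
#' FALSE and splice-site features are unavailable).
#'
#' @param path GTF (`.gtf`) or BED (`.bed`) file.
#' @param biotype_filter character vector of gene biotypes to retain
#'   (default `"protein_coding"`); `NULL` disables the filter. Ignored for
#'   BED input.
#' @return named list of `gene_model` objects. Exon coordinates are stored
#'   0-based half-open; exons are sorted by genomic coordinate.
#' @export
load_gene_models <- function(path, biotype_filter = "protein_coding") {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    models <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      id <- if (!is.null(g$name) && !is.na(g$name)) g$name else paste0("region_", i)
      strand <- as.character(BiocGenerics::strand(g))
      if (!strand %in% c("+", "-")) strand <- "+"
      ex <- cbind(start = BiocGenerics::start(g) - 1L, end = BiocGenerics::end(g))
      new_gene_model(id, as.character(GenomicRanges::seqnames(g)), strand,
                     biotype = NA_character_,
                     transcripts = list(list(transcript_id = id, exons = ex)),
                     structure_known = FALSE)
    })
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    if (!length(models)) warning("no regions loaded from ", path)
    return(models)
  }

  check_gtf_lines(path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) {
    warning("no exon records in ", path)
    return(structure(list(), names = character(0)))
  }
  bt <- ex$gene_biotype %||% ex$gene_type
  if (!is.null(biotype_filter)) {
    if (is.null(bt)) {
      warning("GTF lacks a gene_biotype attribute; biotype filter skipped")
    } else {
      ex <- ex[!is.na(bt) & bt %in% biotype_filter]
    }
  }
  if (!length(ex)) {
    warning("no genes pass the biotype filter")
    return(structure(list(), names = character(0)))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = BiocGenerics::start(ex) - 1L,
                   end = BiocGenerics::end(ex),
                   strand = as.character(BiocGenerics::strand(ex)),
                   gene_id = ex$gene_id,
                   transcript_id = ex$transcript_id,
                   biotype = if (is.null(ex$gene_biotype %||% ex$gene_type))
                     NA_character_ else (ex$gene_biotype %||% ex$gene_type),
                   stringsAsFactors = FALSE)
  models <- lapply(split(df, df$gene_id), function(gdf) {
    txs <- lapply(split(gdf, gdf$transcript_id), function(tdf) {
      tdf <- tdf[order(tdf$start), , drop = FALSE]
      list(transcript_id = tdf$transcript_id[1L],
           exons = cbind(start = tdf$start, end = tdf$end))
    })
    new_gene_model(gdf$gene_id[1L], gdf$chrom[1L], gdf$strand[1L],
                   gdf$biotype[1L], txs)
  })
  models[order(names(models))]
}

gene_span <- function(model) {
  rng <- range(unlist(lapply(model$transcripts, function(tx) tx$exons)))
  c(start = rng[1L], end = rng[2L]) # 0-based half-open
}

#' Classify a genomic position against a transcript
#'
#' Returns one of `donor`, `acceptor`, `exon`, `intron`, `intergenic`.
#' Donor/acceptor windows take precedence over exon/intron; when the two
#' site windows of a short intron or exon both cover the position, the
#' nearer splice site wins and ties go to the donor. Minus-strand
#' transcripts mirror the plus-strand rule in transcript sense.
#'
#' @param pos 1-based genomic position.
#' @param transcript transcript element of a `gene_model` (list with an
#'   `exons` matrix, 0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param cfg a [region_config()].
#' @return character scalar region class.
#' @export
classify_region <- function(pos, transcript, strand, cfg = region_config()) {
  if (!is.finite(pos) || pos < 1) stop("position off the chromosome: ", pos)
  ex <- transcript$exons
  p <- as.integer(pos) - 1L
  n <- nrow(ex)
  if (p < ex[1L, 1L] || p >= ex[n, 2L]) return("intergenic")

  de <- cfg$donor_exonic_nt; di <- cfg$donor_intronic_nt
  ae <- cfg$acceptor_exonic_nt; ai <- cfg$acceptor_intronic_nt
  best_class <- NULL; best_dist <- Inf
  consider <- function(class, lo, hi, junction) {
    # window [lo, hi) 0-based; distance to the splice junction coordinate
    if (p >= lo && p < hi) {
      d <- abs(p - junction)
      better <- d < best_dist || (d == best_dist && class == "donor")
      if (better) { best_class <<- class; best_dist <<- d }
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      is <- ex[i, 2L]; ie <- ex[i + 1L, 1L] # intron [is, ie)
      if (strand == "+") {
        consider("donor", is - de, is + di, is)
        consider("acceptor", ie - ai, ie + ae, ie - 1L)
      } else {
        consider("donor", ie - di, ie + de, ie - 1L)
        consider("acceptor", is - ae, is + ai, is)
      }
    }
  }
  if (!is.null(best_class)) return(best_class)
  if (any(p >= ex[, 1L] & p < ex[, 2L])) "exon" else "intron"
}

#' Locate the intron containing a position
#'
#' @param pos 1-based genomic position.
#' @param transcript transcript element of a `gene_model`.
#' @param strand `"+"` or `"-"` (determines transcript sense).
#' @return `NULL` when the position is exonic or outside the transcript;
#'   otherwise a list with `intron` (0-based half-open c(start, end)),
#'   `length`, `index` (intron number in genomic order), and 1-based
#'   transcript-sense distances `d5` (to the 5' splice site; first intronic
#'   base has `d5 = 1`) and `d3` (to the 3' splice site; last intronic base
#'   has `d3 = 1`).
#' @export
intron_context <- function(pos, transcript, strand = "+") {
  ex <- transcript$exons
  p <- as.integer(pos) - 1L
  n <- nrow(ex)
  if (n < 2L || p < ex[1L, 1L] || p >= ex[n, 2L]) return(NULL)
  for (i in seq_len(n - 1L)) {
    is <- unname(ex[i, 2L]); ie <- unname(ex[i + 1L, 1L])
    if (p >= is && p < ie) {
      len <- ie - is
      off_left <- p - is + 1L  # 1-based offset from genomic-left intron end
      off_right <- ie - p      # 1-based offset from genomic-right intron end
      if (strand == "+") {
        return(list(intron = c(start = is, end = ie), length = len,
                    index = i, d5 = off_left, d3 = off_right))
      } else {
        return(list(intron = c(start = is, end = ie), length = len,
                    index = i, d5 = off_right, d3 = off_left))
      }
    }
  }
  NULL
}

# Transcript-sense nt distances from a 1-based position to the nearest donor
# and acceptor junctions of a transcript (location features for the model).
splice_site_distances <- function(pos, transcript, strand = "+") {
  ex <- transcript$exons
  n <- nrow(ex)
  p <- as.integer(pos) - 1L
  if (n < 2L) return(c(dist_donor = NA_real_, dist_acceptor = NA_real_))
  donors <- acceptors <- numeric(0)
  for (i in seq_len(n - 1L)) {
    is <- ex[i, 2L]; ie <- ex[i + 1L, 1L]
    if (strand == "+") {
      donors <- c(donors, is)       # first intronic base of the donor side
      acceptors <- c(acceptors, ie - 1L) # last intronic base of acceptor side
    } else {
      donors <- c(donors, ie - 1L)
      acceptors <- c(acceptors, is)
    }
  }
  c(dist_donor = min(abs(p - donors)), dist_acceptor = min(abs(p - acceptors)))
}

# Region class of a variant across all covering transcripts; the most
# splice-proximal class wins (donor > acceptor > exon > intron). Per-
# transcript calls are retained in the `hits` data frame.
classify_variant_region <- function(chrom, pos, models, cfg = region_config()) {
  prec <- c(donor = 1, acceptor = 2, exon = 3, intron = 4, intergenic = 5)
  hits <- list()
  for (m in models) {
    if (m$chrom != chrom) next
    span <- gene_span(m)
    if (pos - 1L < span["start"] || pos - 1L >= span["end"]) next
    for (tx in m$transcripts) {
      cls <- classify_region(pos, tx, m$strand, cfg)
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = m$gene_id, transcript_id = tx$transcript_id,
        strand = m$strand, region = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(list(region = "intergenic",
                hits = data.frame(gene_id = character(0),
                                  transcript_id = character(0),
                                  strand = character(0),
                                  region = character(0))))
  hits <- do.call(rbind, hits)
  hits <- hits[order(prec[hits$region]), , drop = FALSE]
  list(region = hits$region[1L], hits = hits)
}
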