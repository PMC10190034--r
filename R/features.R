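# Bespoke splice features: AG/GT creation-removal flags, AG exclusion zone
# membership with the branchpoint-proximity subcase, U12 intron flag,
# minimal-intron violation, and assembly of the per-variant feature vector.

#' Branchpoint / AG-exclusion-zone configuration
#'
#' @param window_min,window_max branchpoint search window, nt upstream of
#'   the 3' splice site (defaults 18 and 44). `window_max` proxies the
#'   branchpoint position when no branchpoint table is supplied.
#' @param agez_bp_margin margin in nt: an AG created closer than this to the
#'   branchpoint marks the exon-skipping-prone subcase (default 15).
#' @param min_intron_nt minimal intron length in nt (default 45).
#' @return object of class `branchpoint_config`.
#' @export
branchpoint_config <- function(window_min = 18L, window_max = 44L,
                               agez_bp_margin = 15L, min_intron_nt = 45L) {
  if (window_min >= window_max) stop("window_min must be < window_max")
  if (min_intron_nt <= 0) stop("min_intron_nt must be positive")
  structure(list(window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 agez_bp_margin = as.integer(agez_bp_margin),
                 min_intron_nt = as.integer(min_intron_nt)),
            class = "branchpoint_config")
}

count_dinuc <- function(s, dinuc) {
  n <- nchar(s)
  if (n < 2L) return(0L)
  hits <- gregexpr(paste0("(?=", dinuc, ")"), s, perl = TRUE)[[1]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' Detect AG/GT dinucleotide creation or removal
#'
#' Compares the dinucleotide content of the affected window (changed bases
#' plus one flanking base each side) between the reference and alternate
#' haplotypes, in transcript sense. Created means the alternate haplotype
#' carries more of the dinucleotide than the reference; removed the
#' converse; assessed independently for AG and GT.
#'
#' @param v single-row variant data.frame.
#' @param chromseq reference chromosome sequence.
#' @param strand transcript strand.
#' @return named logical vector `ag_created`, `ag_removed`, `gt_created`,
#'   `gt_removed`.
#' @export
detect_ag_gt_change <- function(v, chromseq, strand = "+") {
  win <- variant_windows(chromseq, v, 1L)
  ref <- win$ref; alt <- win$alt
  if (strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  rag <- count_dinuc(ref, "AG"); aag <- count_dinuc(alt, "AG")
  rgt <- count_dinuc(ref, "GT"); agt <- count_dinuc(alt, "GT")
  c(ag_created = aag > rag, ag_removed = rag > aag,
    gt_created = agt > rgt, gt_removed = rgt > agt)
}

# Representative 1-based genomic position of a variant (first changed base;
# the insertion point for pure insertions).
variant_position <- function(v) variant_core(v)$start

#' AG exclusion zone membership and branchpoint distance
#'
#' The AG exclusion zone (AGEZ) runs from the branchpoint (exclusive) to the
#' acceptor AG (exclusive). The branchpoint position comes from an external
#' per-intron table when available; otherwise `window_max` nt upstream of
#' the 3' splice site proxies it. An AG created inside the zone marks a
#' candidate cryptic acceptor; when the new AG lies closer than
#' `agez_bp_margin` nt to the branchpoint the subcase is exon-skipping-prone
#' rather than new-splice-site use.
#'
#' @param v single-row variant data.frame.
#' @param transcript transcript element of a `gene_model`.
#' @param strand transcript strand.
#' @param bp_pos 1-based genomic position of the branchpoint adenosine for
#'   the containing intron, or `NULL`/`NA` when unknown.
#' @param cfg a [branchpoint_config()].
#' @return list with `in_agez` (logical), `bp_distance` (nt between variant
#'   and branchpoint, `NA` for exonic variants) and `skip_prone` (logical,
#'   `NA` when not applicable).
#' @export
in_ag_exclusion_zone <- function(v, transcript, strand = "+", bp_pos = NULL,
                                 cfg = branchpoint_config()) {
  ic <- intron_context(variant_position(v), transcript, strand)
  if (is.null(ic))
    return(list(in_agez = FALSE, bp_distance = NA_real_, skip_prone = NA))
  d3 <- ic$d3
  b <- if (!is.null(bp_pos) && !is.na(bp_pos)) {
    bp_ic <- intron_context(bp_pos, transcript, strand)
    if (is.null(bp_ic)) cfg$window_max else bp_ic$d3
  } else cfg$window_max
  in_agez <- d3 >= 3L && d3 < b       # acceptor AG (d3 1-2) and bp excluded
  bp_distance <- abs(b - d3)
  list(in_agez = in_agez, bp_distance = bp_distance,
       skip_prone = in_agez && bp_distance < cfg$agez_bp_margin)
}

#' Load U12 (minor spliceosome) intron intervals from BED
#'
#' @param path BED file of U12 intron intervals.
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
load_u12_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' U12 intron membership flag
#'
#' TRUE iff the variant's containing intron overlaps a listed U12 interval;
#' FALSE in any other intron; `NA` (feature missing, not FALSE) when no U12
#' interval set was provided or the variant is not intronic.
#'
#' @param v single-row variant data.frame.
#' @param transcript transcript element; @param strand transcript strand.
#' @param chrom chromosome name of the variant.
#' @param u12 data.frame from [load_u12_bed()], or `NULL`.
#' @return logical scalar (possibly `NA`).
#' @export
u12_flag <- function(v, transcript, strand, chrom, u12 = NULL) {
  if (is.null(u12)) return(NA)
  ic <- intron_context(variant_position(v), transcript, strand)
  if (is.null(ic)) return(NA)
  rows <- u12[u12$chrom == chrom, , drop = FALSE]
  if (!nrow(rows)) return(FALSE)
  any(rows$start < ic$intron["end"] & rows$end > ic$intron["start"])
}

#' Minimal-intron violation flag
#'
#' TRUE iff the variant is an intronic deletion that shrinks its containing
#' intron below the minimal intron length (`min_intron_nt`, default 45 nt):
#' `intron_length - deleted_intronic_nt < min_intron_nt`. Any non-deletion
#' returns FALSE.
#'
#' @inheritParams u12_flag
#' @param cfg a [branchpoint_config()] (supplies `min_intron_nt`).
#' @return logical scalar.
#' @export
min_intron_violation <- function(v, transcript, strand = "+",
                                 cfg = branchpoint_config()) {
  if (v$vclass != "deletion") return(FALSE)
  core <- variant_core(v)
  ic <- intron_context(core$start, transcript, strand)
  if (is.null(ic)) return(FALSE)
  del_lo <- core$start - 1L                      # 0-based half-open span
  del_hi <- core$start - 1L + nchar(core$ref)
  deleted_in_intron <- max(0L, min(del_hi, ic$intron["end"]) -
                             max(del_lo, ic$intron["start"]))
  (ic$length - deleted_in_intron) < cfg$min_intron_nt
}

#' Load a branchpoint table
#'
#' Tab-separated columns `chrom`, `three_prime_ss` (1-based genomic
#' coordinate of the intron's transcript-sense last base) and `bp_pos`
#' (1-based genomic position of the branchpoint adenosine), e.g. exported
#' from a branchpoint predictor.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
load_branchpoints <- function(path) {
  bp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "three_prime_ss", "bp_pos")
  if (!all(need %in% names(bp)))
    stop("branchpoint table must have columns ", paste(need, collapse = ", "))
  bp
}

# 1-based genomic coordinate of an intron's transcript-sense 3'SS base.
intron_three_prime_ss <- function(ic, strand) {
  if (strand == "+") unname(ic$intron["end"]) else unname(ic$intron["start"] + 1L)
}

#' Assemble feature vectors for a set of variants
#'
#' Runs the full bespoke annotation for each variant: region class and
#' splice-site distances, per-motif PWM deltas (exonic and near-exonic
#' variants only; missing elsewhere), AG/GT change flags, AG-exclusion-zone
#' features, U12 and minimal-intron flags, and the external predictor
#' scores (complex variants are decomposed and per-category scores combined
#' with the max rule). Missing values are preserved as `NA`; nothing is
#' imputed.
#'
#' @param variants variant data.frame (already region-filtered; a variant
#'   outside all gene models is an error).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param models gene models from [load_gene_models()].
#' @param pwms PWM set (default [default_pwms()]).
#' @param score_tables named list of score tables from [load_score_table()].
#' @param u12 U12 intervals from [load_u12_bed()], or `NULL` (feature
#'   missing).
#' @param branchpoints branchpoint table from [load_branchpoints()], or
#'   `NULL` (fixed-window proxy).
#' @param region_cfg a [region_config()].
#' @param bp_cfg a [branchpoint_config()].
#' @return data.frame, one row per variant, keyed by `variant_id`.
#' @export
build_feature_vectors <- function(variants, genome, models,
                                  pwms = default_pwms(),
                                  score_tables = list(),
                                  u12 = NULL, branchpoints = NULL,
                                  region_cfg = region_config(),
                                  bp_cfg = branchpoint_config()) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  genome <- vapply(genome, toupper, character(1))
  prec <- c(donor = 1, acceptor = 2, exon = 3, intron = 4)

  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    pos <- variant_position(v)
    cls <- classify_variant_region(v$chrom, pos, models, region_cfg)
    hits <- cls$hits
    hits <- hits[hits$region != "intergenic", , drop = FALSE]
    if (!nrow(hits))
      stop("variant outside all gene models (filter first): ", v$id)
    hit <- hits[which.min(prec[hits$region]), , drop = FALSE]
    model <- models[[hit$gene_id]]
    tx <- NULL
    for (t in model$transcripts) if (t$transcript_id == hit$transcript_id) tx <- t
    strand <- model$strand
    chromseq <- genome[[v$chrom]]
    if (is.null(chromseq)) stop("chromosome missing from genome: ", v$chrom)

    dists <- splice_site_distances(pos, tx, strand)
    ic <- intron_context(pos, tx, strand)

    # ESE/ESS deltas only for exonic and near-exonic positions
    pwm_vals <- stats::setNames(rep(NA_real_, length(pwms)),
                                paste0("pwm_", names(pwms)))
    for (p in names(pwms)) {
      w <- pwms[[p]]$width
      near_exonic <- is.null(ic) || min(ic$d5, ic$d3) <= w
      if (near_exonic) {
        pwm_vals[paste0("pwm_", p)] <-
          pwm_delta_variant(v, chromseq, pwms[[p]], strand)
      }
    }

    aggt <- detect_ag_gt_change(v, chromseq, strand)

    bp_pos <- NULL
    if (!is.null(branchpoints) && !is.null(ic)) {
      ss <- intron_three_prime_ss(ic, strand)
      m <- branchpoints[branchpoints$chrom == v$chrom &
                          branchpoints$three_prime_ss == ss, , drop = FALSE]
      if (nrow(m)) bp_pos <- m$bp_pos[1L]
    }
    agez <- in_ag_exclusion_zone(v, tx, strand, bp_pos, bp_cfg)

    ext <- external_scores_for_variant(v, score_tables)

    rows[[i]] <- c(
      list(variant_id = v$id, region = cls$region,
           dist_donor = unname(dists["dist_donor"]),
           dist_acceptor = unname(dists["dist_acceptor"])),
      as.list(pwm_vals),
      as.list(aggt),
      list(in_agez = agez$in_agez,
           agez_skip_prone = isTRUE(aggt[["ag_created"]]) &&
             isTRUE(agez$skip_prone),
           bp_distance = agez$bp_distance,
           u12 = u12_flag(v, tx, strand, v$chrom, u12),
           min_intron_violation = min_intron_violation(v, tx, strand, bp_cfg)),
      as.list(ext))
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
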