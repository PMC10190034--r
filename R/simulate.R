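# Synthetic fixture generator: toy genome with canonical splice motifs,
# gene models, variants planted in every region class, class-conditional
# external-tool scores with region-dependent missingness, and truth labels
# derived from a latent delta-PSI. Everything is deterministic per seed.

#' Synthetic data configuration
#'
#' The defaults define the package's reference study conditions: a toy
#' genome of 30 five-exon protein-coding genes (mixed strands), 2000
#' variants split across donor/acceptor/exon/intron classes with about
#' two thirds designated splice-disrupting, a latent delta-PSI effect
#' (|effect| ~ N(0.45, 0.15), null ~ N(0, 0.03)) thresholded at the 10%
#' transcript-change rule to produce binary labels, and external-tool
#' scores separated between classes by `tool_separation` with
#' region-dependent missingness (precomputed-style tools only score
#' canonical splice regions).
#'
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @param n_genes,exons_per_gene toy genome geometry.
#' @param exon_length_range,intron_length_range,intergenic_gap lengths, nt.
#' @param n_variants named counts per region class
#'   (donor/acceptor/exon/intron).
#' @param effect_fraction proportion of variants per class planted as
#'   splice-disrupting (assigned a delta-PSI effect draw).
#' @param dpsi_effect_mean,dpsi_effect_sd,dpsi_null_sd latent delta-PSI
#'   distribution parameters.
#' @param dpsi_label_threshold |delta-PSI| at or above which a variant is
#'   labelled splice-altering (default 0.10).
#' @param tool_separation class-conditional mean shift of simulated tool
#'   scores, on each tool's own scale (0 = uninformative).
#' @param missingness baseline per-tool missing-score probability.
#' @param label_mode `"planted"` ties effect draws to the planted
#'   disruptive variants (sequence features informative); `"random"`
#'   assigns them uniformly at random (sequence features uninformative).
#' @param af_missing_rate fraction of variants without a population AF.
#' @param u12_fraction fraction of introns marked as minor-spliceosome.
#' @param export_dpsi also write the latent delta-PSI into the truth TSV
#'   (default FALSE: only the thresholded binary label is exported).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 30L, exons_per_gene = 5L,
                             exon_length_range = c(90L, 150L),
                             intron_length_range = c(70L, 200L),
                             intergenic_gap = 200L,
                             n_variants = c(donor = 400L, acceptor = 500L,
                                            exon = 700L, intron = 400L),
                             effect_fraction = 0.66,
                             dpsi_effect_mean = 0.45, dpsi_effect_sd = 0.15,
                             dpsi_null_sd = 0.03,
                             dpsi_label_threshold = 0.10,
                             tool_separation = 0.6,
                             missingness = 0.05,
                             label_mode = c("planted", "random"),
                             af_missing_rate = 0.1,
                             u12_fraction = 0.05,
                             export_dpsi = FALSE) {
  label_mode <- match.arg(label_mode)
  stopifnot(dpsi_label_threshold > 0, dpsi_label_threshold < 1,
            effect_fraction >= 0, effect_fraction <= 1,
            missingness >= 0, missingness <= 1)
  if (!all(c("donor", "acceptor", "exon", "intron") %in% names(n_variants)))
    stop("n_variants needs counts named donor, acceptor, exon, intron")
  structure(as.list(environment()), class = "synthetic_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substr_set <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

# Build one transcript-sense intron: canonical GT...AG ends, a branchpoint
# adenosine 25 nt upstream of the 3'SS and an AG-free exclusion zone.
build_intron <- function(len) {
  s <- rand_dna(len)
  s <- substr_set(s, 1L, "GT")
  s <- substr_set(s, len - 1L, "AG")
  bp_at <- len - 24L                      # d3 = 25 for the branchpoint A
  s <- substr_set(s, bp_at - 3L, "CTAACT") # CTA[A]CT: the A lands on bp_at
  # scrub AG dinucleotides between branchpoint and acceptor (the AGEZ)
  for (j in (bp_at + 1L):(len - 3L)) {
    if (substr(s, j, j + 1L) == "AG")
      s <- substr_set(s, j + 1L, "C")
  }
  list(seq = s, bp_offset = bp_at)        # transcript-sense 1-based offset
}

#' Generate the toy genome and gene models
#'
#' Writes (when `dir` is given) a FASTA, a GTF of protein-coding gene
#' models, a branchpoint TSV and a U12-intron BED, and returns the
#' generating structures in memory. Every intron starts GT and ends AG in
#' transcript sense; strands alternate so minus-strand handling is always
#' exercised; a high-scoring enhancer motif is planted in internal exons
#' so ESE-disrupting variants exist.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory, or `NULL` to skip writing files.
#' @return list: `genome` (named character), `models` (gene models),
#'   `introns` / `exons` / `ese` metadata data.frames, `paths`.
#' @export
generate_genome_and_models <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  pwms <- default_pwms()
  ese_pwm <- pwms[[1L]]
  ese_motif <- paste(colnames(ese_pwm$mat)[apply(ese_pwm$mat, 1L, which.max)],
                     collapse = "")
  chrom <- "chrS1"
  genome_parts <- character(0)
  cursor <- 0L                            # 0-based length so far
  models <- list()
  introns <- exons <- ese <- list()

  for (g in seq_len(cfg$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%02d", g)
    ex_len <- sample(cfg$exon_length_range[1L]:cfg$exon_length_range[2L],
                     cfg$exons_per_gene, replace = TRUE)
    in_len <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L],
                     cfg$exons_per_gene - 1L, replace = TRUE)
    seqs <- character(0)
    ts_exon_bounds <- matrix(0L, cfg$exons_per_gene, 2L)
    ts_intron_bounds <- matrix(0L, cfg$exons_per_gene - 1L, 2L)
    bp_offsets <- integer(cfg$exons_per_gene - 1L)
    ese_bounds <- list()
    off <- 0L
    for (e in seq_len(cfg$exons_per_gene)) {
      es <- rand_dna(ex_len[e])
      if (e > 1L && e < cfg$exons_per_gene &&
          ex_len[e] >= 20L + nchar(ese_motif)) {
        es <- substr_set(es, 15L, ese_motif)
        ese_bounds[[length(ese_bounds) + 1L]] <-
          c(off + 15L, off + 14L + nchar(ese_motif))
      }
      seqs <- c(seqs, es)
      ts_exon_bounds[e, ] <- c(off + 1L, off + ex_len[e])
      off <- off + ex_len[e]
      if (e < cfg$exons_per_gene) {
        intr <- build_intron(in_len[e])
        seqs <- c(seqs, intr$seq)
        ts_intron_bounds[e, ] <- c(off + 1L, off + in_len[e])
        bp_offsets[e] <- off + intr$bp_offset
        off <- off + in_len[e]
      }
    }
    gene_ts <- paste(seqs, collapse = "")
    L <- nchar(gene_ts)
    gene_genomic <- if (strand == "+") gene_ts else revcomp(gene_ts)
    gap <- rand_dna(cfg$intergenic_gap)
    genome_parts <- c(genome_parts, gap, gene_genomic)
    gene_start0 <- cursor + cfg$intergenic_gap  # 0-based gene start
    cursor <- gene_start0 + L

    # transcript-sense 1-based [a, b] -> genomic 0-based half-open
    ts2gen <- function(a, b) {
      if (strand == "+") c(gene_start0 + a - 1L, gene_start0 + b)
      else c(gene_start0 + (L - b), gene_start0 + (L - a + 1L))
    }
    ex_gen <- t(apply(ts_exon_bounds, 1L, function(r) ts2gen(r[1L], r[2L])))
    ord <- order(ex_gen[, 1L])
    models[[gid]] <- new_gene_model(
      gid, chrom, strand, "protein_coding",
      list(list(transcript_id = paste0(gid, ".t1"),
                exons = cbind(start = ex_gen[ord, 1L], end = ex_gen[ord, 2L]))))
    exons[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               start = ex_gen[ord, 1L], end = ex_gen[ord, 2L],
                               stringsAsFactors = FALSE)
    for (k in seq_len(cfg$exons_per_gene - 1L)) {
      ig <- ts2gen(ts_intron_bounds[k, 1L], ts_intron_bounds[k, 2L])
      bp <- ts2gen(bp_offsets[k], bp_offsets[k])
      three_ss <- if (strand == "+") ig[2L] else ig[1L] + 1L
      introns[[length(introns) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = ig[1L], end = ig[2L], length = ig[2L] - ig[1L],
        bp_pos = bp[1L] + 1L, three_prime_ss = three_ss,
        u12 = stats::runif(1) < cfg$u12_fraction, stringsAsFactors = FALSE)
    }
    for (eb in ese_bounds) {
      eg <- ts2gen(eb[1L], eb[2L])
      ese[[length(ese) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = eg[1L], end = eg[2L], stringsAsFactors = FALSE)
    }
  }
  genome <- stats::setNames(paste(genome_parts, collapse = ""), chrom)
  out <- list(genome = genome, models = models,
              introns = do.call(rbind, introns),
              exons = do.call(rbind, exons),
              ese = do.call(rbind, ese),
              ese_pwm = ese_pwm, paths = list())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
    gtf <- file.path(dir, "models.gtf")
    write_gtf(models, gtf)
    bp <- file.path(dir, "branchpoints.tsv")
    utils::write.table(out$introns[, c("chrom", "three_prime_ss", "bp_pos")],
                       bp, sep = "\t", quote = FALSE, row.names = FALSE)
    u12 <- file.path(dir, "u12.bed")
    u12df <- out$introns[out$introns$u12, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\tU12_intron", u12df$chrom,
                       u12df$start, u12df$end), u12)
    out$paths <- list(fasta = fa, gtf = gtf, branchpoints = bp, u12 = u12)
  }
  out
}

write_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    sp <- gene_span(m)
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', m$gene_id,
                      m$biotype %||% "protein_coding")
    lines <- c(lines, paste(m$chrom, "splicetree_sim", "gene",
                            sp["start"] + 1L, sp["end"], ".", m$strand, ".",
                            attr_g, sep = "\t"))
    for (tx in m$transcripts) {
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                        m$gene_id, tx$transcript_id,
                        m$biotype %||% "protein_coding")
      lines <- c(lines, paste(m$chrom, "splicetree_sim", "transcript",
                              tx$exons[1L, 1L] + 1L,
                              tx$exons[nrow(tx$exons), 2L], ".", m$strand,
                              ".", attr_t, sep = "\t"))
      for (e in seq_len(nrow(tx$exons))) {
        lines <- c(lines, paste(m$chrom, "splicetree_sim", "exon",
                                tx$exons[e, 1L] + 1L, tx$exons[e, 2L], ".",
                                m$strand, ".", attr_t, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
}

# transcript-sense intronic offset (1-based from the 5'SS) -> 1-based
# genomic position
intron_offset_to_genomic <- function(intron, offset, from = c("d5", "d3")) {
  from <- match.arg(from)
  if (from == "d5") {
    if (intron$strand == "+") intron$start + offset
    else intron$end - offset + 1L
  } else {
    if (intron$strand == "+") intron$end - offset + 1L
    else intron$start + offset
  }
}

genomic_base <- function(genome, chrom, pos) substr(genome[[chrom]], pos, pos)

ts_base <- function(genome, chrom, pos, strand) {
  b <- genomic_base(genome, chrom, pos)
  if (strand == "-") revcomp(b) else b
}

#' Plant variants in every region class
#'
#' Plants, per the configured class quotas: canonical donor GT / acceptor
#' AG SNVs, window-background SNVs, ESE-disrupting exonic SNVs against the
#' shipped PWMs, exonic MNVs, AG-creating SNVs inside the AG exclusion
#' zone, minimal-intron-violating deletions, deep-intronic background SNVs
#' and intronic insdels. A latent delta-PSI is drawn per variant (effect
#' distribution for designated disruptive variants, null otherwise) and
#' thresholded into the binary truth label.
#'
#' @param cfg a [synthetic_config()].
#' @param sim output of [generate_genome_and_models()].
#' @param dir output directory for `variants.vcf` + `truth.tsv`, or `NULL`.
#' @return truth data.frame: variant columns plus `region_planted`,
#'   `planted_type`, `designated`, `dpsi`, `label`, `af_popmax`.
#' @export
generate_variants <- function(cfg, sim, dir = NULL) {
  set.seed(cfg$seed + 1L)
  genome <- sim$genome
  introns <- sim$introns
  used <- new.env(parent = emptyenv())
  rows <- list()
  bases <- c("A", "C", "G", "T")

  take <- function(chrom, pos, ref, alt, region, type, designated) {
    key <- variant_key(chrom, pos, ref, alt)
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      vclass = variant_class(ref, alt), id = key,
      region_planted = region, planted_type = type,
      designated = designated, stringsAsFactors = FALSE)
    TRUE
  }

  snv_at <- function(pos, chrom = "chrS1") {
    ref <- genomic_base(genome, chrom, pos)
    alt <- sample(setdiff(bases, ref), 1L)
    list(ref = ref, alt = alt)
  }

  plant <- function(region, n_total, plant_disruptive, plant_background) {
    k <- round(cfg$effect_fraction * n_total)
    for (i in seq_len(n_total)) {
      ok <- FALSE; tries <- 0L
      while (!ok) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("region capacity exhausted while planting ", region,
               " variants; enlarge the toy genome")
        ok <- if (i <= k) plant_disruptive() else plant_background()
      }
    }
  }

  rand_intron <- function(min_len = 0L) {
    cand <- introns[introns$length >= min_len, , drop = FALSE]
    cand[sample(nrow(cand), 1L), , drop = FALSE]
  }

  ## donor class -------------------------------------------------------
  plant("donor", cfg$n_variants[["donor"]],
    plant_disruptive = function() {
      it <- rand_intron()
      off <- sample(1:2, 1L)                      # the canonical GT
      pos <- intron_offset_to_genomic(it, off, "d5")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "donor", "donor_site", TRUE)
    },
    plant_background = function() {
      it <- rand_intron()
      off <- sample(3:6, 1L)
      pos <- intron_offset_to_genomic(it, off, "d5")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "donor", "donor_window", FALSE)
    })

  ## acceptor class ----------------------------------------------------
  plant("acceptor", cfg$n_variants[["acceptor"]],
    plant_disruptive = function() {
      it <- rand_intron()
      off <- sample(1:2, 1L)                      # the canonical AG
      pos <- intron_offset_to_genomic(it, off, "d3")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "acceptor", "acceptor_site", TRUE)
    },
    plant_background = function() {
      it <- rand_intron()
      off <- sample(3:12, 1L)
      pos <- intron_offset_to_genomic(it, off, "d3")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "acceptor", "acceptor_window", FALSE)
    })

  ## exon class --------------------------------------------------------
  ese <- sim$ese
  ese_pwm <- sim$ese_pwm
  exdf <- sim$exons
  n_exon <- cfg$n_variants[["exon"]]
  n_mnv <- round(0.1 * n_exon)
  plant("exon", n_exon - n_mnv,
    plant_disruptive = function() {
      e <- ese[sample(nrow(ese), 1L), , drop = FALSE]
      j <- sample(ese_pwm$width, 1L)              # motif position, ts sense
      pos <- if (e$strand == "+") e$start + j else e$end - j + 1L
      worst <- colnames(ese_pwm$mat)[which.min(ese_pwm$mat[j, ])]
      alt_ts <- worst
      ref <- genomic_base(genome, e$chrom, pos)
      alt <- if (e$strand == "-") revcomp(alt_ts) else alt_ts
      if (alt == ref) return(FALSE)
      take(e$chrom, pos, ref, alt, "exon", "ese_disrupt", TRUE)
    },
    plant_background = function() {
      ex <- exdf[sample(nrow(exdf), 1L), , drop = FALSE]
      width <- ex$end - ex$start
      if (width < 60L) return(FALSE)
      off <- sample(35:(width - 20L), 1L)         # clear of site windows
      pos <- ex$start + off
      a <- snv_at(pos)
      take(ex$chrom, pos, a$ref, a$alt, "exon", "exon_background", FALSE)
    })
  plant("exon", n_mnv,
    plant_disruptive = function() {
      ex <- exdf[sample(nrow(exdf), 1L), , drop = FALSE]
      width <- ex$end - ex$start
      if (width < 60L) return(FALSE)
      off <- sample(35:(width - 20L), 1L)
      pos <- ex$start + off
      ref <- substr(genome[[ex$chrom]], pos, pos + 1L)
      alt <- paste0(sample(setdiff(bases, substr(ref, 1L, 1L)), 1L),
                    sample(setdiff(bases, substr(ref, 2L, 2L)), 1L))
      take(ex$chrom, pos, ref, alt, "exon", "exon_mnv", TRUE)
    },
    plant_background = function() {
      ex <- exdf[sample(nrow(exdf), 1L), , drop = FALSE]
      width <- ex$end - ex$start
      if (width < 60L) return(FALSE)
      off <- sample(35:(width - 20L), 1L)
      pos <- ex$start + off
      ref <- substr(genome[[ex$chrom]], pos, pos + 1L)
      alt <- paste0(sample(setdiff(bases, substr(ref, 1L, 1L)), 1L),
                    sample(setdiff(bases, substr(ref, 2L, 2L)), 1L))
      take(ex$chrom, pos, ref, alt, "exon", "exon_mnv", FALSE)
    })

  ## intron class ------------------------------------------------------
  n_intron <- cfg$n_variants[["intron"]]
  n_del <- round(0.15 * n_intron)
  n_insdel <- round(0.1 * n_intron)
  n_agez <- round(0.25 * n_intron)
  n_deep <- n_intron - n_del - n_insdel - n_agez

  # AG-creating SNVs inside the AG exclusion zone
  plant("intron", n_agez,
    plant_disruptive = function() {
      it <- rand_intron()
      d3 <- sample(4:20, 1L)                      # inside AGEZ (bp at 25)
      pos <- intron_offset_to_genomic(it, d3, "d3")
      prev <- intron_offset_to_genomic(it, d3 + 1L, "d3")
      if (ts_base(genome, it$chrom, prev, it$strand) != "A") return(FALSE)
      ref <- genomic_base(genome, it$chrom, pos)
      alt <- if (it$strand == "-") revcomp("G") else "G"
      if (alt == ref) return(FALSE)
      take(it$chrom, pos, ref, alt, "intron", "agez_ag_create", TRUE)
    },
    plant_background = function() {
      it <- rand_intron()
      d3 <- sample(4:20, 1L)
      pos <- intron_offset_to_genomic(it, d3, "d3")
      a <- snv_at(pos)
      ts_alt <- if (it$strand == "-") revcomp(a$alt) else a$alt
      if (ts_alt == "G") return(FALSE)            # avoid accidental AG gain
      take(it$chrom, pos, a$ref, a$alt, "intron", "agez_background", FALSE)
    })

  # minimal-intron-violating deletions (and matched small deletions)
  plant("intron", n_del,
    plant_disruptive = function() {
      it <- rand_intron(min_len = 80L)
      del_len <- it$length - (branchpoint_config()$min_intron_nt - 8L)
      d5_from <- 4L
      if (d5_from + del_len - 1L > it$length - 30L) return(FALSE)
      gpos <- sort(c(intron_offset_to_genomic(it, d5_from, "d5"),
                     intron_offset_to_genomic(it, d5_from + del_len - 1L, "d5")))
      anchor <- gpos[1L] - 1L
      ref <- substr(genome[[it$chrom]], anchor, gpos[2L])
      alt <- substr(genome[[it$chrom]], anchor, anchor)
      take(it$chrom, anchor, ref, alt, "intron", "min_intron_del", TRUE)
    },
    plant_background = function() {
      it <- rand_intron(min_len = 90L)
      d5_from <- sample(8:12, 1L)
      del_len <- 5L
      gpos <- sort(c(intron_offset_to_genomic(it, d5_from, "d5"),
                     intron_offset_to_genomic(it, d5_from + del_len - 1L, "d5")))
      anchor <- gpos[1L] - 1L
      ref <- substr(genome[[it$chrom]], anchor, gpos[2L])
      alt <- substr(genome[[it$chrom]], anchor, anchor)
      take(it$chrom, anchor, ref, alt, "intron", "small_intron_del", FALSE)
    })

  # intronic insdels (complex variants)
  plant("intron", n_insdel,
    plant_disruptive = function() {
      it <- rand_intron(min_len = 100L)
      d5 <- sample(25:35, 1L)
      gpos <- sort(c(intron_offset_to_genomic(it, d5, "d5"),
                     intron_offset_to_genomic(it, d5 + 1L, "d5")))
      ref <- substr(genome[[it$chrom]], gpos[1L], gpos[2L])
      alt <- paste0(sample(setdiff(bases, substr(ref, 1L, 1L)), 1L),
                    sample(bases, 1L),
                    sample(setdiff(bases, substr(ref, 2L, 2L)), 1L))
      take(it$chrom, gpos[1L], ref, alt, "intron", "intron_insdel", TRUE)
    },
    plant_background = function() {
      it <- rand_intron(min_len = 100L)
      d5 <- sample(36:45, 1L)
      gpos <- sort(c(intron_offset_to_genomic(it, d5, "d5"),
                     intron_offset_to_genomic(it, d5 + 1L, "d5")))
      ref <- substr(genome[[it$chrom]], gpos[1L], gpos[2L])
      alt <- paste0(sample(setdiff(bases, substr(ref, 1L, 1L)), 1L),
                    sample(bases, 1L),
                    sample(setdiff(bases, substr(ref, 2L, 2L)), 1L))
      take(it$chrom, gpos[1L], ref, alt, "intron", "intron_insdel", FALSE)
    })

  # deep intronic background SNVs
  plant("intron", n_deep,
    plant_disruptive = function() {
      it <- rand_intron(min_len = 120L)
      d5 <- sample(10:(it$length - 50L), 1L)
      pos <- intron_offset_to_genomic(it, d5, "d5")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "intron", "deep_intron", TRUE)
    },
    plant_background = function() {
      it <- rand_intron(min_len = 120L)
      d5 <- sample(10:(it$length - 50L), 1L)
      pos <- intron_offset_to_genomic(it, d5, "d5")
      a <- snv_at(pos)
      take(it$chrom, pos, a$ref, a$alt, "intron", "deep_intron", FALSE)
    })

  truth <- do.call(rbind, rows)

  if (cfg$label_mode == "random")
    truth$designated <- sample(truth$designated)

  n <- nrow(truth)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  effect <- sign * rnorm_clip(n, cfg$dpsi_effect_mean, cfg$dpsi_effect_sd, 0, 1)
  # non-designated variants emulate validated non-splice-altering variants:
  # by the curation rule their transcript change sits below the labelling
  # threshold, so the null delta-PSI is truncated just under it
  null_cap <- cfg$dpsi_label_threshold - 1e-6
  null <- rnorm_clip(n, 0, cfg$dpsi_null_sd, -null_cap, null_cap)
  truth$dpsi <- ifelse(truth$designated, effect, null)
  truth$label <- ifelse(abs(truth$dpsi) >= cfg$dpsi_label_threshold,
                        "positive", "negative")
  truth$af_popmax <- 10^stats::runif(n, -6, log10(0.009))
  truth$af_popmax[stats::runif(n) < cfg$af_missing_rate] <- NA_real_

  ord <- order(truth$chrom, truth$pos, truth$ref, truth$alt)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf <- file.path(dir, "variants.vcf")
    write_simple_vcf(truth, vcf)
    tsv <- file.path(dir, "truth.tsv")
    cols <- c("id", "label", if (isTRUE(cfg$export_dpsi)) "dpsi")
    utils::write.table(truth[, cols, drop = FALSE], tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    attr(truth, "paths") <- list(vcf = vcf, truth = tsv)
  }
  truth
}

write_simple_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=splicetree_sim",
           "##INFO=<ID=AF_POPMAX,Number=1,Type=Float,Description=\"Simulated population popmax allele frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  info <- ifelse(is.na(variants$af_popmax), ".",
                 paste0("AF_POPMAX=", fmt_num(variants$af_popmax)))
  recs <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", ".", info, sep = "\t")
  writeLines(c(hdr, recs), path)
}

unit_draw <- function(n, pos, sep, base = 0.12, sd = 0.1) {
  rnorm_clip(n, base + ifelse(pos, sep, 0), sd, 0, 1)
}

#' Simulate external-tool score tables
#'
#' Draws class-conditional scores per tool (clipped Gaussians separated by
#' `tool_separation` on each tool's own scale, same spread in both classes)
#' with region-dependent missingness: precomputed-style tools (dbscSNV,
#' SPIDEX) only score canonical donor/acceptor regions, CADD and
#' Spliceogen only score simple substitutions, the branchpoint tool only
#' intronic variants, and the deep-learning tools score complex variants
#' through their decomposition parts only (exercising the max rule).
#'
#' @param cfg a [synthetic_config()].
#' @param truth truth data.frame from [generate_variants()].
#' @param dir output directory for `scores_<tool>.tsv` files, or `NULL`.
#' @return named list of score tables (as loaded by [load_score_table()]).
#' @export
simulate_tool_scores <- function(cfg, truth, dir = NULL) {
  set.seed(cfg$seed + 2L)
  sep <- cfg$tool_separation
  pos <- truth$label == "positive"
  canonical <- truth$region_planted %in% c("donor", "acceptor")
  complexv <- truth$vclass %in% c("MNV", "insdel")
  snv <- truth$vclass == "SNV"
  n <- nrow(truth)

  key_df <- function(rows) {
    data.frame(chrom = truth$chrom[rows], pos = truth$pos[rows],
               ref = ifelse(nzchar(truth$ref[rows]), truth$ref[rows], "-"),
               alt = ifelse(nzchar(truth$alt[rows]), truth$alt[rows], "-"),
               stringsAsFactors = FALSE)
  }
  miss <- function(rows) rows[stats::runif(length(rows)) >= cfg$missingness]

  # deep-learning tools: simple variants directly, complex via parts
  dl_rows <- function() {
    simple <- miss(which(!complexv))
    parts <- lapply(which(complexv), function(i) {
      p <- decompose_complex(truth[i, , drop = FALSE])
      p$posflag <- pos[i]
      p
    })
    list(simple = simple, parts = parts)
  }

  tables <- list()

  ## spliceai: four delta categories, one "active" per variant
  dl <- dl_rows()
  build_spliceai <- function(keys, posflag) {
    m <- length(posflag)
    out <- cbind(keys,
                 DS_AG = unit_draw(m, FALSE, 0, base = 0.03, sd = 0.03),
                 DS_AL = unit_draw(m, FALSE, 0, base = 0.03, sd = 0.03),
                 DS_DG = unit_draw(m, FALSE, 0, base = 0.03, sd = 0.03),
                 DS_DL = unit_draw(m, FALSE, 0, base = 0.03, sd = 0.03))
    active <- sample(c("DS_AG", "DS_AL", "DS_DG", "DS_DL"), m, replace = TRUE)
    for (cat in unique(active)) {
      sel <- active == cat
      out[sel, cat] <- unit_draw(sum(sel), posflag[sel], sep)
    }
    out
  }
  sa_simple <- build_spliceai(key_df(dl$simple), pos[dl$simple])
  sa_parts <- do.call(rbind, lapply(dl$parts, function(p) {
    build_spliceai(data.frame(chrom = p$chrom, pos = p$pos,
                              ref = ifelse(nzchar(p$ref), p$ref, "-"),
                              alt = ifelse(nzchar(p$alt), p$alt, "-"),
                              stringsAsFactors = FALSE),
                   rep(p$posflag[1L], nrow(p)))
  }))
  tables$spliceai <- rbind(sa_simple, sa_parts)

  ## mmsplice: delta logit PSI, effect shifts negative
  dl2 <- dl_rows()
  mm_rows <- function(keys, posflag) {
    cbind(keys, delta_logit_psi = rnorm_clip(length(posflag),
                                             ifelse(posflag, -4 * sep, 0),
                                             0.8, -15, 15))
  }
  tables$mmsplice <- rbind(
    mm_rows(key_df(dl2$simple), pos[dl2$simple]),
    do.call(rbind, lapply(dl2$parts, function(p) {
      mm_rows(data.frame(chrom = p$chrom, pos = p$pos,
                         ref = ifelse(nzchar(p$ref), p$ref, "-"),
                         alt = ifelse(nzchar(p$alt), p$alt, "-"),
                         stringsAsFactors = FALSE),
              rep(p$posflag[1L], nrow(p)))
    })))

  ## spliceogen: substitutions only
  rows <- miss(which(snv | truth$vclass == "MNV"))
  tables$spliceogen <- cbind(key_df(rows),
                             score = unit_draw(length(rows), pos[rows], sep))

  ## cadd: SNVs only
  rows <- miss(which(snv))
  tables$cadd <- cbind(key_df(rows),
                       phred = rnorm_clip(length(rows),
                                          5 + ifelse(pos[rows], 28 * sep, 0),
                                          4, 0, 99))

  ## spidex: SNVs in canonical splice regions only
  rows <- miss(which(snv & canonical))
  tables$spidex <- cbind(key_df(rows),
                         dpsi_zscore = rnorm_clip(length(rows),
                                                  ifelse(pos[rows], -7 * sep, 0),
                                                  1.5, -20, 20))

  ## dbscsnv: SNVs in canonical splice regions only
  rows <- miss(which(snv & canonical))
  tables$dbscsnv <- cbind(key_df(rows),
                          ada_score = unit_draw(length(rows), pos[rows], sep),
                          rf_score = unit_draw(length(rows), pos[rows], sep))

  ## branchpointer: intron-class variants only
  rows <- miss(which(truth$region_planted == "intron"))
  tables$branchpointer <- cbind(key_df(rows),
                                bp_prob = unit_draw(length(rows), pos[rows],
                                                    sep))

  # distinct complex variants can share a decomposition part; keep one row
  # per normalised key per tool (the loader requires unique keys)
  for (tool in names(tables)) {
    df <- tables[[tool]]
    key <- variant_key(df$chrom, df$pos, ifelse(df$ref == "-", "", df$ref),
                       ifelse(df$alt == "-", "", df$alt))
    tables[[tool]] <- df[!duplicated(key), , drop = FALSE]
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tool in names(tables)) {
      df <- tables[[tool]]
      num_cols <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
      for (cc in num_cols) df[[cc]] <- fmt_num(df[[cc]])
      utils::write.table(df, file.path(dir, paste0("scores_", tool, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(tables)
}
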