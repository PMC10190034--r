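# Bespoke splice-rule features.

test_that("AG/GT change detection matches dinucleotide enumeration", {
  v <- vrow("c", 3, "T", "G")          # AATT -> AAGT
  expect_equal(detect_ag_gt_change(v, "AATT"),
               c(ag_created = TRUE, ag_removed = FALSE,
                 gt_created = TRUE, gt_removed = FALSE))
  v2 <- vrow("c", 2, "AG", "A")        # CAGT -> CAT: AG (and GT) removed
  res <- detect_ag_gt_change(v2, "CAGT")
  expect_true(res[["ag_removed"]])
  v3 <- vrow("c", 2, "C", "T")         # CCCC -> CTCC
  expect_equal(unname(detect_ag_gt_change(v3, "CCCC")), rep(FALSE, 4L))
})

test_that("an SNV and its exact reversion mirror created/removed flags", {
  set.seed(51)
  for (i in 1:25) {
    chromseq <- rand_seq(30)
    pos <- sample(5:25, 1)
    ref <- substr(chromseq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- detect_ag_gt_change(vrow("c", pos, ref, alt), chromseq)
    alt_genome <- apply_to_seq(chromseq, pos, ref, alt)
    rev <- detect_ag_gt_change(vrow("c", pos, alt, ref), alt_genome)
    expect_equal(fwd[["ag_created"]], rev[["ag_removed"]])
    expect_equal(fwd[["ag_removed"]], rev[["ag_created"]])
    expect_equal(fwd[["gt_created"]], rev[["gt_removed"]])
    expect_equal(fwd[["gt_removed"]], rev[["gt_created"]])
  }
})

test_that("minus-strand sequence features equal plus-strand on the reverse complement", {
  set.seed(52)
  for (i in 1:15) {
    chromseq <- rand_seq(60)
    pos <- sample(20:40, 1)
    ref <- substr(chromseq, pos, pos + sample(0:2, 1))
    alt <- rand_seq(nchar(ref))
    if (substr(alt, 1, 1) == substr(ref, 1, 1) ||
        substr(alt, nchar(alt), nchar(alt)) == substr(ref, nchar(ref), nchar(ref)))
      next
    v <- vrow("c", pos, ref, alt)
    # mirrored universe: reverse-complement genome, variant at reflected locus
    L <- nchar(chromseq)
    rc_genome <- revcomp(chromseq)
    rc_pos <- L - (pos + nchar(ref) - 1) + 1
    v_rc <- vrow("c", rc_pos, revcomp(ref), revcomp(alt))
    expect_equal(detect_ag_gt_change(v, chromseq, strand = "-"),
                 detect_ag_gt_change(v_rc, rc_genome, strand = "+"))
    pwm <- rand_pwm(5)
    expect_equal(pwm_delta_variant(v, chromseq, pwm, strand = "-"),
                 pwm_delta_variant(v_rc, rc_genome, pwm, strand = "+"),
                 tolerance = 1e-12)
  }
})

test_that("AG exclusion zone membership and the 15-nt branchpoint margin", {
  # intron 1001..1100 on the plus strand; 3'SS at 1100
  tx <- make_tx(c(901, 1101), c(1000, 1200))
  mk <- function(pos) vrow("c", pos, "A", "G")
  # branchpoint 30 nt upstream of the 3'SS (position 1071, d3 = 30)
  bp <- 1071
  res <- in_ag_exclusion_zone(mk(1081), tx, "+", bp_pos = bp)  # d3 = 20
  expect_true(res$in_agez)
  expect_equal(res$bp_distance, 10)
  expect_true(res$skip_prone)       # < 15 nt from the branchpoint
  res2 <- in_ag_exclusion_zone(mk(1096), tx, "+", bp_pos = bp) # d3 = 5
  expect_true(res2$in_agez)
  expect_equal(res2$bp_distance, 25)
  expect_false(res2$skip_prone)     # >= 15 nt: new-splice-site subcase
  # upstream of the branchpoint: not in the zone
  res3 <- in_ag_exclusion_zone(mk(1061), tx, "+", bp_pos = bp) # d3 = 40
  expect_false(res3$in_agez)
  # the acceptor AG itself is excluded
  expect_false(in_ag_exclusion_zone(mk(1099), tx, "+", bp_pos = bp)$in_agez)
  # exonic variant: no zone, missing distance
  ex <- in_ag_exclusion_zone(mk(950), tx, "+", bp_pos = bp)
  expect_false(ex$in_agez)
  expect_true(is.na(ex$bp_distance))
  # without a branchpoint the window_max proxy (44 nt) applies
  res4 <- in_ag_exclusion_zone(mk(1081), tx, "+")
  expect_true(res4$in_agez)
  expect_equal(res4$bp_distance, 24)
})

test_that("U12 membership is missing without an interval set", {
  tx <- make_tx(c(901, 1101), c(1000, 1200))
  v <- vrow("c", 1050, "A", "G")
  expect_true(is.na(u12_flag(v, tx, "+", "c", NULL)))
  u12 <- data.frame(chrom = "c", start = 1000L, end = 1100L)
  expect_true(u12_flag(v, tx, "+", "c", u12))
  other <- data.frame(chrom = "c", start = 5000L, end = 5100L)
  expect_false(u12_flag(v, tx, "+", "c", other))
})

test_that("minimal-intron violation follows the 45-nt rule", {
  # 100-nt intron 1001..1100
  tx <- make_tx(c(901, 1101), c(1000, 1200))
  seq100 <- rand_seq(1300)
  # 60-nt deletion inside the intron: 100 - 60 = 40 < 45 -> violation
  del60 <- data.frame(chrom = "c", pos = 1009L,
                      ref = substr(seq100, 1009, 1070), alt = substr(seq100, 1009, 1009),
                      vclass = "deletion", id = "d60", stringsAsFactors = FALSE)
  expect_true(min_intron_violation(del60, tx, "+"))
  # 10-nt deletion: 90 >= 45
  del10 <- data.frame(chrom = "c", pos = 1009L,
                      ref = substr(seq100, 1009, 1020), alt = substr(seq100, 1009, 1009),
                      vclass = "deletion", id = "d10", stringsAsFactors = FALSE)
  expect_false(min_intron_violation(del10, tx, "+"))
  expect_false(min_intron_violation(vrow("c", 1050, "A", "G"), tx, "+"))
  # the constant is configurable
  expect_true(min_intron_violation(del10, tx, "+",
                                   branchpoint_config(min_intron_nt = 95)))
})

test_that("assembled feature vectors match direct per-feature calls", {
  set.seed(53)
  # toy gene: two exons around one intron with clean GT/AG ends
  intron_seq <- paste0("GT", rand_seq(76), "AG")
  chromseq <- paste0(rand_seq(100), intron_seq, rand_seq(100))
  tx <- make_tx(c(1, 181), c(100, 280))
  model <- make_model("cT", "+", tx, "gT")
  genome <- c(cT = chromseq)
  v <- rbind(vrow("cT", 50, substr(chromseq, 50, 50),
                  setdiff(c("A", "C", "G", "T"), substr(chromseq, 50, 50))[1]),
             vrow("cT", 140, substr(chromseq, 140, 140),
                  setdiff(c("A", "C", "G", "T"), substr(chromseq, 140, 140))[1]))
  pwms <- default_pwms()
  f <- build_feature_vectors(v, genome, list(gT = model), pwms = pwms)
  expect_equal(f$variant_id, v$id)
  expect_equal(f$region, c("exon", "intron"))
  # compose-vs-direct: exonic PWM delta and AG/GT flags
  expect_equal(f$pwm_SRSF1_syn[1],
               pwm_delta_variant(v[1, ], chromseq, pwms$SRSF1_syn, "+"))
  aggt <- detect_ag_gt_change(v[2, ], chromseq, "+")
  expect_equal(f$ag_created[2], unname(aggt["ag_created"]))
  expect_equal(f$gt_removed[2], unname(aggt["gt_removed"]))
  # deep-intronic variant: PWM deltas are missing (not defaulted)
  expect_true(is.na(f$pwm_SRSF1_syn[2]))
  # no score tables given: all external features missing
  expect_true(all(is.na(unlist(f[, splicetree:::tool_feature_names()]))))
  # booleans never missing inside transcripts
  expect_false(anyNA(f$ag_created))
  expect_false(anyNA(f$in_agez))
  # determinism
  f2 <- build_feature_vectors(v, genome, list(gT = model), pwms = pwms)
  expect_identical(f, f2)
  # a variant outside every model is an error (should have been filtered)
  expect_error(build_feature_vectors(vrow("cT", 290, "A", "C"), genome,
                                     list(gT = model), pwms = pwms),
               "outside")
})
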