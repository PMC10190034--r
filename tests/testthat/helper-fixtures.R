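# Small fixture builders shared across test files. Everything is built in
# code; no binary fixtures.

# A transcript from 1-based inclusive exon coordinates.
make_tx <- function(starts, ends, id = "t1") {
  list(transcript_id = id,
       exons = cbind(start = as.integer(starts) - 1L, end = as.integer(ends)))
}

make_model <- function(chrom, strand, tx, gene_id = "g1",
                       biotype = "protein_coding") {
  splicetree:::new_gene_model(gene_id, chrom, strand, biotype, list(tx))
}

vrow <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = variant_class(ref, alt),
             af_popmax = NA_real_,
             id = variant_key(chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

write_tmp_vcf <- function(records, info = rep(".", length(records)),
                          path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, info = ".") {
  paste(chrom, pos, ".", ref, alt, ".", ".", info, sep = "\t")
}

# A random PWM with weights in [-2, 2].
rand_pwm <- function(width, name = "rand") {
  mat <- matrix(stats::runif(width * 4, -2, 2), width, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  structure(list(name = name, width = width, role = "enhancer",
                 threshold = 0, mat = mat), class = "pwm")
}

# A small labelled feature frame with a clean signal on f1 and noise f2.
toy_training <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  data.frame(f1 = ifelse(y, 1, 0) + stats::rnorm(n, 0, 0.05),
             f2 = stats::rnorm(n),
             label = ifelse(y, "positive", "negative"),
             stringsAsFactors = FALSE)
}
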