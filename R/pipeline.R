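# End-to-end pipeline runners behind the command-line interface:
# annotate -> train -> score -> evaluate, plus the annotated-VCF/TSV
# writers. Every runner is pure with respect to its inputs: identical
# inputs (and seed) produce byte-identical outputs, so provenance embeds
# the package version and a config hash but never a timestamp (run times
# are logged to stderr instead).

pkg_version <- function() {
  as.character(utils::packageVersion("splicetree"))
}

#' Write an annotated VCF (and TSV mirror)
#'
#' Emits one record per variant with INFO keys `ST_SCORE` (final 0-1
#' splice-altering score), `ST_REGION` and `ST_F_<feature>` for every
#' feature column. Numeric values are formatted canonically (6 significant
#' digits), booleans as 0/1 and missing values as `.`, so re-reading the
#' file reproduces every value bit-exactly as formatted.
#'
#' @param variants variant data.frame (row-aligned with `features`).
#' @param features feature data.frame from [build_feature_vectors()].
#' @param scores numeric final scores (or `NA` for unscored variants).
#' @param path output VCF path.
#' @param tsv_path optional path for the flat TSV mirror.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, features, scores, path,
                                tsv_path = NULL) {
  if (nrow(variants) != nrow(features) ||
      nrow(variants) != length(scores))
    stop("variants, features and scores must be aligned")
  feat_cols <- setdiff(names(features), c("variant_id", "region"))
  fmt_col <- function(col) {
    if (is.logical(features[[col]])) fmt_bool(features[[col]])
    else if (is.numeric(features[[col]])) fmt_num(features[[col]])
    else ifelse(is.na(features[[col]]), ".", as.character(features[[col]]))
  }
  fmtd <- lapply(feat_cols, fmt_col)
  names(fmtd) <- feat_cols
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=splicetree-", pkg_version()),
           "##INFO=<ID=ST_SCORE,Number=1,Type=Float,Description=\"Splice-altering consensus score (0-1)\">",
           "##INFO=<ID=ST_REGION,Number=1,Type=String,Description=\"Splice region class\">",
           vapply(feat_cols, function(cc) sprintf(
             "##INFO=<ID=ST_F_%s,Number=1,Type=String,Description=\"Splice feature %s\">",
             cc, cc), character(1)),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    kv <- c(paste0("ST_SCORE=", fmt_num(scores[i])),
            paste0("ST_REGION=", features$region[i]),
            vapply(feat_cols, function(cc)
              paste0("ST_F_", cc, "=", fmtd[[cc]][i]), character(1)))
    paste(kv, collapse = ";")
  }, character(1))
  recs <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, variants$id,
          ifelse(nzchar(variants$ref), variants$ref, "-"),
          ifelse(nzchar(variants$alt), variants$alt, "-"),
          ".", ".", info, sep = "\t")
  } else character(0)
  writeLines(c(hdr, recs), path)
  if (!is.null(tsv_path)) {
    tsv <- data.frame(variant_id = features$variant_id,
                      region = features$region,
                      stringsAsFactors = FALSE)
    for (cc in feat_cols) tsv[[cc]] <- fmtd[[cc]]
    tsv$ST_SCORE <- fmt_num(scores)
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back an annotated VCF
#'
#' Returns the `ST_*` INFO payload as formatted strings (the writer's
#' canonical formatting), keyed by variant id — the inverse of
#' [write_annotated_vcf()] for round-trip checks and downstream joins.
#'
#' @param path annotated VCF path.
#' @return data.frame: id plus one character column per INFO key.
#' @export
read_annotated_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lines[!startsWith(lines, "#")]
  if (!length(recs)) {
    return(data.frame(id = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(recs, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 3L)
  kvs <- lapply(fields, function(f) {
    pairs <- strsplit(strsplit(f[[8L]], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(pairs, `[`, character(1), 2L),
                    vapply(pairs, `[`, character(1), 1L))
  })
  keys <- unique(unlist(lapply(kvs, names)))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (k in keys) out[[k]] <- vapply(kvs, function(x) x[[k]] %||% ".", character(1))
  out
}

#' Run the full simulation stage
#'
#' Writes the complete synthetic universe (FASTA, GTF, branchpoint TSV,
#' U12 BED, VCF, truth TSV, per-tool score TSVs) into a directory; all
#' paths are consumable by the other runners unmodified.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory.
#' @return list with `paths` (named file paths) and the in-memory `truth`.
#' @export
run_simulate <- function(cfg, dir) {
  sim <- generate_genome_and_models(cfg, dir)
  truth <- generate_variants(cfg, sim, dir)
  simulate_tool_scores(cfg, truth, dir)
  tools <- names(tool_schemas())
  score_paths <- stats::setNames(
    file.path(dir, paste0("scores_", tools, ".tsv")), tools)
  message("simulated ", nrow(truth), " variants over ", cfg$n_genes,
          " genes (seed ", cfg$seed, ")")
  list(paths = c(sim$paths, attr(truth, "paths"),
                 list(scores = score_paths)),
       truth = truth, sim = sim)
}

#' Annotate a VCF with splice features
#'
#' Executes the filtering and annotation flow: load gene models, read and
#' normalise the VCF, subset to gene regions, apply the allele-frequency
#' filter, compute the bespoke splice features and join the external score
#' tables. Filter counts are logged to stderr.
#'
#' @param vcf input VCF path.
#' @param fasta reference FASTA path.
#' @param gtf gene models (GTF or BED) path.
#' @param score_paths named character vector tool -> score TSV (optional).
#' @param out_prefix when given, writes `<prefix>.features.tsv`.
#' @param af_max allele-frequency cutoff (default 0.01).
#' @param u12_bed,branchpoint_tsv optional auxiliary annotation paths.
#' @param biotype_filter gene biotype filter for the GTF.
#' @return list: `variants` (filtered data.frame), `features` (data.frame).
#' @export
run_annotate <- function(vcf, fasta, gtf, score_paths = character(0),
                         out_prefix = NULL, af_max = 0.01,
                         u12_bed = NULL, branchpoint_tsv = NULL,
                         biotype_filter = "protein_coding") {
  for (p in c(vcf, fasta, gtf)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  models <- load_gene_models(gtf, biotype_filter)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  variants <- read_vcf(vcf)
  n0 <- nrow(variants)
  variants <- filter_by_regions(variants, models)
  n1 <- nrow(variants)
  variants <- filter_by_af(variants, filter_config(af_max = af_max))
  n2 <- nrow(variants)
  message("variants: ", n0, " read, ", n1, " in gene regions, ", n2,
          " after AF filter (af_max=", af_max, ")")
  tables <- list()
  for (tool in names(score_paths)) {
    if (file.exists(score_paths[[tool]]))
      tables[[tool]] <- load_score_table(score_paths[[tool]], tool)
  }
  u12 <- if (!is.null(u12_bed)) load_u12_bed(u12_bed) else NULL
  bps <- if (!is.null(branchpoint_tsv)) load_branchpoints(branchpoint_tsv) else NULL
  features <- build_feature_vectors(variants, genome, models,
                                    score_tables = tables, u12 = u12,
                                    branchpoints = bps)
  if (!is.null(out_prefix)) {
    utils::write.table(format_feature_tsv(features),
                       paste0(out_prefix, ".features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(variants = variants, features = features)
}

# Canonical text formatting of a feature frame (deterministic output).
format_feature_tsv <- function(features) {
  out <- features
  for (cc in names(out)) {
    if (is.logical(out[[cc]])) out[[cc]] <- fmt_bool(out[[cc]])
    else if (is.numeric(out[[cc]])) out[[cc]] <- fmt_num(out[[cc]])
    else out[[cc]][is.na(out[[cc]])] <- "."
  }
  out
}

#' Read a feature TSV back into typed columns
#'
#' @param path feature TSV written by [run_annotate()] (optionally with a
#'   `label` column appended for training).
#' @return typed data.frame (`.` decoded to `NA`).
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = ".", colClasses = "character")
  bool_cols <- c("ag_created", "ag_removed", "gt_created", "gt_removed",
                 "in_agez", "agez_skip_prone", "u12", "min_intron_violation")
  for (cc in names(df)) {
    if (cc %in% c("variant_id", "region", "label")) next
    if (cc %in% bool_cols) df[[cc]] <- df[[cc]] == "1"
    else df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}

#' Default model feature registry
#'
#' The ordered feature set entering the consensus model: location features
#' first (region class and splice-site distances dominate importance),
#' then the bespoke sequence features, then the external tool scores.
#'
#' @param pwm_names motif names of the PWM set in use.
#' @return character vector of feature column names.
#' @export
default_feature_registry <- function(pwm_names = names(default_pwms())) {
  c("region", "dist_donor", "dist_acceptor",
    paste0("pwm_", pwm_names),
    "ag_created", "ag_removed", "gt_created", "gt_removed",
    "in_agez", "agez_skip_prone", "bp_distance", "u12",
    "min_intron_violation", tool_feature_names())
}

#' Train the consensus model with cross-validation
#'
#' @param features labelled feature data.frame (feature columns + `label`),
#'   or a path to a feature TSV with a label column.
#' @param out_prefix when given, writes `<prefix>.model.json`,
#'   `<prefix>.cv.json` and `<prefix>.importance.tsv`.
#' @param folds number of CV folds (default 10).
#' @param seed fold seed.
#' @param params a [tree_params()].
#' @param registry feature registry (default [default_feature_registry()]
#'   intersected with available columns).
#' @return list: `model` (`splice_tree`), `cv` (see [cross_validate()]),
#'   `importance`.
#' @export
run_train <- function(features, out_prefix = NULL, folds = 10L, seed = 1L,
                      params = tree_params(seed = seed), registry = NULL) {
  if (is.character(features)) features <- read_feature_tsv(features)
  if (!"label" %in% names(features)) stop("training data needs a label column")
  if (is.null(registry))
    registry <- intersect(default_feature_registry(), names(features))
  cv <- cross_validate(features, k = folds, params = params, seed = seed,
                       features = registry)
  model <- train_tree(features, params = params, features = registry)
  imp <- feature_importance(model)
  message("trained on ", nrow(features), " variants; ", folds,
          "-fold CV mean auROC ", round(cv$mean_auroc, 4),
          ", mean auPRC ", round(cv$mean_auprc, 4))
  if (!is.null(out_prefix)) {
    save_model(model, paste0(out_prefix, ".model.json"))
    jsonlite::write_json(
      list(provenance = list(tool = "splicetree", version = pkg_version(),
                             config_hash = st_hash(c(registry, folds, seed))),
           folds = folds, seed = seed,
           per_fold = cv$metrics,
           mean_auroc = cv$mean_auroc, mean_auprc = cv$mean_auprc),
      paste0(out_prefix, ".cv.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE)
    utils::write.table(
      data.frame(feature = names(imp), importance = fmt_num(imp)),
      paste0(out_prefix, ".importance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  list(model = model, cv = cv, importance = imp)
}

#' Score variants with a trained model
#'
#' Predicts the decision-tree score for each feature vector, applies the
#' zero rule for variants unscored by both deep-learning score groups, and
#' (optionally) writes the annotated VCF, the TSV mirror and a BED of
#' impacted regions for calls at or above the threshold.
#'
#' @param variants,features aligned data.frames from [run_annotate()].
#' @param model a `splice_tree` or path to a saved model.
#' @param out_prefix when given, writes `<prefix>.scored.vcf`,
#'   `<prefix>.scored.tsv` and `<prefix>.calls.bed`.
#' @param threshold calling threshold (default 0.61; calls are
#'   `score >= threshold`).
#' @return data.frame: `variant_id`, `region`, `model_score`, `score`,
#'   `call`.
#' @export
run_score <- function(variants, features, model, out_prefix = NULL,
                      threshold = 0.61) {
  if (is.character(model)) model <- load_model(model)
  model_score <- predict_score(model, features)
  final <- vapply(seq_len(nrow(features)), function(i)
    apply_zero_rule(features[i, , drop = FALSE], model_score[i]),
    numeric(1))
  res <- data.frame(variant_id = features$variant_id,
                    region = features$region,
                    model_score = model_score, score = final,
                    call = final >= threshold, stringsAsFactors = FALSE)
  message(sum(res$call), "/", nrow(res), " variants called splice-altering",
          " at threshold ", threshold)
  if (!is.null(out_prefix)) {
    write_annotated_vcf(variants, features, final,
                        paste0(out_prefix, ".scored.vcf"),
                        paste0(out_prefix, ".scored.tsv"))
    called <- which(res$call)
    bed <- sprintf("%s\t%d\t%d\t%s\t%s", variants$chrom[called],
                   pmax(variants$pos[called] - 50L, 0L),
                   variants$pos[called] + 50L,
                   variants$id[called], fmt_num(final[called]))
    writeLines(bed, paste0(out_prefix, ".calls.bed"))
  }
  res
}

#' Evaluate scored variants against truth labels
#'
#' Builds the precision-recall curve and emits the calibration report:
#' F1-optimal threshold with its sensitivity/specificity, the threshold at
#' a target specificity, the threshold at a target precision, auPRC/auROC
#' and region-stratified recall.
#'
#' @param scored data.frame from [run_score()] (or scored TSV path, where
#'   the score column is `ST_SCORE`).
#' @param truth data.frame with `id` and `label` columns (or truth TSV
#'   path).
#' @param out_prefix when given, writes `<prefix>.report.json` and
#'   `<prefix>.pr.csv`.
#' @param specificity_target high-specificity operating point (default
#'   0.975).
#' @param precision_target precision bar for cross-tool comparison
#'   (default 0.95).
#' @param threshold default calling threshold used for stratified recall
#'   (default 0.61).
#' @return list of calibration results (see details in the report JSON).
#' @export
run_evaluate <- function(scored, truth, out_prefix = NULL,
                         specificity_target = 0.975,
                         precision_target = 0.95, threshold = 0.61) {
  if (is.character(scored)) {
    tsv <- utils::read.delim(scored, stringsAsFactors = FALSE)
    scored <- data.frame(variant_id = tsv$variant_id, region = tsv$region,
                         score = as.numeric(tsv$ST_SCORE),
                         stringsAsFactors = FALSE)
  }
  if (is.character(truth)) truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  m <- match(scored$variant_id, truth$id)
  if (anyNA(m)) stop("scored variant(s) missing from truth: ",
                     scored$variant_id[which(is.na(m))[1L]])
  labels <- truth$label[m]
  curve <- pr_curve(scored$score, labels)
  f1 <- f1_optimal_threshold(curve)
  hs <- threshold_at_specificity(curve, specificity_target)
  tp95 <- threshold_at_precision(curve, precision_target)
  strat <- stratified_recall(scored$score, labels, scored$region, threshold)
  report <- list(
    provenance = list(tool = "splicetree", version = pkg_version(),
                      config_hash = st_hash(c(specificity_target,
                                              precision_target, threshold))),
    n = nrow(scored), n_pos = curve$n_pos, n_neg = curve$n_neg,
    auprc = curve$auprc, auroc = roc_auc(scored$score, labels),
    f1_optimal = f1,
    high_specificity = hs,
    precision_target = precision_target,
    threshold_at_precision = tp95,
    stratified_recall = strat)
  if (!is.null(out_prefix)) {
    jsonlite::write_json(report, paste0(out_prefix, ".report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null", pretty = TRUE)
    utils::write.csv(curve$points, paste0(out_prefix, ".pr.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report
}
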