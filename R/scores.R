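# Ingestion of external splice-predictor score tables: canonical per-tool
# schemas, key-normalised joins, the complex-variant max rule and the
# unscored-variant zero rule. The tools themselves are never executed;
# their outputs are consumed as tables.

#' Canonical external-tool score schemas
#'
#' One column set per supported tool, with the documented score range used
#' for validation at load time. Deep-learning delta categories (the
#' spliceai-style layout) are kept as four separate features; the max rule
#' applies only to complex-variant decomposition, not feature construction.
#'
#' @return named list: per tool, `columns` and `range` (list of c(lo, hi)).
#' @export
tool_schemas <- function() {
  list(
    spliceai = list(columns = c("DS_AG", "DS_AL", "DS_DG", "DS_DL"),
                    range = c(0, 1)),
    mmsplice = list(columns = "delta_logit_psi", range = c(-15, 15)),
    spliceogen = list(columns = "score", range = c(0, 1)),
    cadd = list(columns = "phred", range = c(0, 99)),
    spidex = list(columns = "dpsi_zscore", range = c(-20, 20)),
    dbscsnv = list(columns = c("ada_score", "rf_score"), range = c(0, 1)),
    branchpointer = list(columns = "bp_prob", range = c(0, 1))
  )
}

# Feature column names contributed by a tool (tool_column).
tool_feature_names <- function(tools = names(tool_schemas())) {
  schemas <- tool_schemas()
  unlist(lapply(tools, function(t) paste(t, schemas[[t]]$columns, sep = "_")),
         use.names = FALSE)
}

#' Load an external predictor score table
#'
#' Tab-separated input with key columns `chrom`, `pos`, `ref`, `alt` and the
#' tool's declared score columns. Allele fields use `-` for an empty allele
#' (decomposed insertion/deletion parts). Keys are normalised exactly as
#' the VCF reader normalises variants, so joins are exact. Duplicate keys
#' and out-of-range scores are errors.
#'
#' @param path TSV file.
#' @param tool one of `names(tool_schemas())`.
#' @return data.frame keyed by `id`, with class `score_table` and the tool
#'   name in attribute `tool`.
#' @export
load_score_table <- function(path, tool) {
  schemas <- tool_schemas()
  tool <- match.arg(tool, names(schemas))
  sch <- schemas[[tool]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character", alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", sch$columns)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("score table for ", tool, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$ref <- ifelse(df$ref == "-", "", toupper(df$ref))
  df$alt <- ifelse(df$alt == "-", "", toupper(df$alt))
  if (nrow(df)) {
    norm <- Map(normalize_allele, df$pos, df$ref, df$alt)
    df$pos <- vapply(norm, `[[`, numeric(1), "pos")
    df$ref <- vapply(norm, `[[`, character(1), "ref")
    df$alt <- vapply(norm, `[[`, character(1), "alt")
  }
  df$id <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$id))
    stop("duplicate variant key in ", tool, " table: ",
         df$id[duplicated(df$id)][1L])
  for (col in sch$columns) {
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < sch$range[1L] | df[[col]] > sch$range[2L]))
    if (length(bad))
      stop("out-of-range ", col, " in ", tool, " table, row ", bad[1L],
           " (", df[[col]][bad[1L]], " outside [", sch$range[1L], ", ",
           sch$range[2L], "])")
  }
  structure(df[, c("id", sch$columns), drop = FALSE],
            class = c("score_table", "data.frame"), tool = tool)
}

lookup_score <- function(table, id, column) {
  hit <- match(id, table$id)
  if (is.na(hit)) NA_real_ else table[[column]][hit]
}

#' Aggregate part scores for a complex variant
#'
#' For each tool score category scored on at least one decomposition part,
#' the complex variant's score is the maximum over parts; categories scored
#' on no part remain missing.
#'
#' @param v single-row complex variant data.frame.
#' @param parts parts from [decompose_complex()].
#' @param tables named list of `score_table`s.
#' @return named numeric vector (tool_column names).
#' @export
aggregate_complex_scores <- function(v, parts, tables) {
  out <- stats::setNames(rep(NA_real_, length(tool_feature_names(names(tables)))),
                         tool_feature_names(names(tables)))
  schemas <- tool_schemas()
  for (tool in names(tables)) {
    for (col in schemas[[tool]]$columns) {
      vals <- vapply(parts$id, lookup_score, numeric(1),
                     table = tables[[tool]], column = col)
      if (any(!is.na(vals)))
        out[paste(tool, col, sep = "_")] <- max(vals, na.rm = TRUE)
    }
  }
  out
}

# Per-variant external score vector over the full tool registry (columns of
# tools without a table stay NA): direct key lookup, falling back to
# decomposition + max rule for MNV/insdel variants.
external_scores_for_variant <- function(v, tables) {
  feat_names <- tool_feature_names()
  out <- stats::setNames(rep(NA_real_, length(feat_names)), feat_names)
  if (!length(tables)) return(out)
  schemas <- tool_schemas()
  for (tool in names(tables)) {
    for (col in schemas[[tool]]$columns) {
      out[paste(tool, col, sep = "_")] <- lookup_score(tables[[tool]], v$id, col)
    }
  }
  if (v$vclass %in% c("MNV", "insdel")) {
    parts <- decompose_complex(v)
    agg <- aggregate_complex_scores(v, parts, tables)
    for (nm in names(agg)) {
      if (is.na(out[nm]) && !is.na(agg[nm])) out[nm] <- agg[nm]
    }
  }
  out
}

#' Zero rule for unscored variants
#'
#' When both deep-learning score groups (the spliceai-style delta columns
#' and the mmsplice-style column) are entirely missing for a variant, its
#' final score is 0 regardless of the model output; otherwise the model
#' score passes through unchanged. This guards against high-scoring calls
#' built purely on the absence of evidence inside those tools' hard-coded
#' region filters.
#'
#' @param fv single feature-vector row (list or 1-row data.frame).
#' @param model_score decision-tree score in `[0, 1]`.
#' @param groups tool name prefixes whose joint absence triggers the rule.
#' @return final score: 0 or `model_score`.
#' @export
apply_zero_rule <- function(fv, model_score,
                            groups = c("spliceai", "mmsplice")) {
  cols <- unlist(lapply(groups, function(g)
    paste(g, tool_schemas()[[g]]$columns, sep = "_")))
  present <- intersect(cols, names(fv))
  if (!length(present)) return(model_score)
  vals <- unlist(fv[present], use.names = FALSE)
  if (all(is.na(vals))) 0 else model_score
}
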