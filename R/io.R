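#' Read and write the package's TSV interchange formats
#'
#' Count matrices travel as a pair of TSVs: a counts table with genes in
#' rows (first column `gene_id`, then one column per sample) and a sibling
#' metadata table with one row per sample. Score tables are single TSVs with
#' the fixed columns `sample_id`, `true_class`, `condition`, `run_id`,
#' `lab_id`, `replicate_id`, `score`. Size factors are two-column TSVs.
#'
#' @param m a [count_matrix()].
#' @param counts_file,meta_file paths for the counts and metadata TSVs.
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   writers return their path(s) invisibly.
#' @name count_matrix_io
NULL

#' @rdname count_matrix_io
#' @export
write_count_matrix <- function(m, counts_file, meta_file) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, meta_file))
}

#' @rdname count_matrix_io
#' @export
read_count_matrix <- function(counts_file, meta_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") abort("counts TSV must start with `gene_id`")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' @rdname count_matrix_io
#' @param tab a score table (see [as_score_table()]).
#' @param file path of the TSV.
#' @export
write_score_table <- function(tab, file) {
  tab <- as_score_table(tab)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname count_matrix_io
#' @export
read_score_table <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  as_score_table(tab)
}

#' @rdname count_matrix_io
#' @param f named size-factor vector.
#' @export
write_size_factors <- function(f, file) {
  utils::write.table(data.frame(sample_id = names(f), factor = unname(f)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize a linear surrogate classifier
#'
#' The model is written as a TSV of `(gene, weight)` rows preceded by
#' `#`-prefixed header records carrying the intercept, decision threshold
#' and declared score range.
#'
#' @param model a model from [train_classifier()].
#' @param file path.
#' @return the path / the model, invisibly.
#' @export
write_classifier <- function(model, file) {
  stopifnot(inherits(model, "linear_classifier"))
  hdr <- sprintf("# %s\t%.17g", c("intercept", "threshold", "score_range"),
                 c(model$intercept, model$threshold, model$score_range))
  writeLines(c(hdr, "gene\tweight",
               sprintf("%s\t%.17g", names(model$weights),
                       unname(model$weights))), file)
  invisible(file)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines, value = TRUE)
  val <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) abort("model file lacks header record `%s`", key)
    as.numeric(sub(".*\t", "", ln[1]))
  }
  tab <- utils::read.delim(textConnection(lines[!grepl("^# ", lines)]),
                           stringsAsFactors = FALSE)
  w <- tab$weight
  names(w) <- tab$gene
  structure(list(weights = w, intercept = val("intercept"),
                 threshold = val("threshold"),
                 score_range = val("score_range")),
            class = "linear_classifier")
}
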