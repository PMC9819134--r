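# Post-clustering reporting: per-cluster compound sets, cluster-unique
# compound lists, and clinical covariate summaries.

#' Per-cluster compound sets
#'
#' Union of compound names over the samples of each cluster. Presence is
#' binary: a compound belongs to a cluster's set when it appears at least
#' `min_support` times among the cluster's samples.
#'
#' @param compound_table data.frame with columns `sample_id`,
#'   `compound_name` (and optionally `rt`).
#' @param labels named integer vector (or bare vector parallel to
#'   `unique(compound_table$sample_id)`) assigning every sample in the table
#'   a cluster label.
#' @param min_support minimum number of member samples a compound must occur
#'   in (default 1).
#' @return Named list, one character vector of compound names per cluster
#'   label (sorted labels; sorted names).
#' @export
cluster_compound_sets <- function(compound_table, labels, min_support = 1L) {
  lab <- label_lookup(compound_table$sample_id, labels)
  out <- list()
  for (cl in sort(unique(as.integer(labels)))) {
    rows <- compound_table[lab == cl, , drop = FALSE]
    if (nrow(rows)) {
      counts <- table(unique(rows[, c("sample_id", "compound_name")])$compound_name)
      out[[as.character(cl)]] <- sort(names(counts)[counts >= min_support])
    } else out[[as.character(cl)]] <- character(0)
  }
  out
}

label_lookup <- function(sample_ids, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(unique(sample_ids), names(labels))
    if (length(miss))
      stop_fmt("sample '%s' in the compound table has no cluster label", miss[1])
    as.integer(labels[sample_ids])
  } else {
    stop_fmt("labels must be a named vector (sample_id -> label)")
  }
}

#' Cluster-unique compound lists
#'
#' For each cluster, the compounds found in that cluster and in no other —
#' the qualitative fingerprint left after excluding substances recurring
#' across clusters.
#'
#' @param sets named list of per-cluster compound sets
#'   (from [cluster_compound_sets()]); at least 2 clusters.
#' @return Named list of sorted character vectors, pairwise disjoint.
#' @examples
#' unique_compounds(list(`0` = c("x", "y"), `1` = c("y", "z")))
#' @export
unique_compounds <- function(sets) {
  if (length(sets) < 2) stop_fmt("need at least 2 clusters")
  out <- lapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i]))
    sort(setdiff(sets[[i]], others))
  })
  names(out) <- names(sets)
  out
}

#' Per-cluster covariate summaries
#'
#' Clinical-report-style summaries per cluster and covariate: for numeric
#' covariates n, mean, sample SD (n-1; `NA` for single-member groups),
#' median, min, max; for categorical covariates the level counts. Missing
#' values are excluded per covariate, with `n` reflecting complete data.
#'
#' @param covariate_table data.frame with columns `sample_id`, `covariate`,
#'   `value` (character; numeric covariates are detected as columns whose
#'   non-missing values all parse as numbers).
#' @param labels named vector mapping every `sample_id` in the table to a
#'   cluster label.
#' @return A list with `numeric` (data.frame `cluster`, `covariate`, `n`,
#'   `mean`, `sd`, `median`, `min`, `max`) and `categorical` (data.frame
#'   `cluster`, `covariate`, `level`, `count`).
#' @export
summarize_covariates <- function(covariate_table, labels) {
  lab <- label_lookup(covariate_table$sample_id, labels)
  val <- as.character(covariate_table$value)
  num_rows <- list(); cat_rows <- list()
  for (cov in unique(covariate_table$covariate)) {
    sel <- covariate_table$covariate == cov & !is.na(val) & val != ""
    v <- val[sel]; l <- lab[sel]
    suppressWarnings(vn <- as.numeric(v))
    numeric_cov <- length(v) > 0 && !anyNA(vn)
    for (cl in sort(unique(as.integer(labels)))) {
      if (numeric_cov) {
        x <- vn[l == cl]
        num_rows[[length(num_rows) + 1L]] <- data.frame(
          cluster = cl, covariate = cov, n = length(x),
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x) > 1) stats::sd(x) else NA_real_,
          median = if (length(x)) stats::median(x) else NA_real_,
          min = if (length(x)) min(x) else NA_real_,
          max = if (length(x)) max(x) else NA_real_,
          stringsAsFactors = FALSE)
      } else {
        x <- v[l == cl]
        if (length(x)) {
          t <- table(x)
          cat_rows[[length(cat_rows) + 1L]] <- data.frame(
            cluster = cl, covariate = cov, level = names(t),
            count = as.integer(t), stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_num <- data.frame(cluster = integer(0), covariate = character(0),
                          n = integer(0), mean = double(0), sd = double(0),
                          median = double(0), min = double(0), max = double(0))
  empty_cat <- data.frame(cluster = integer(0), covariate = character(0),
                          level = character(0), count = integer(0))
  list(numeric = if (length(num_rows)) do.call(rbind, num_rows) else empty_num,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else empty_cat)
}

#' Published per-cluster compound lists
#'
#' Loads the qualitative per-cluster exhaled-compound lists of the reference
#' 37-patient PAH breathomics cohort shipped with the package
#' (`inst/extdata/pah_cluster_compounds.tsv`), as a named list of character
#' vectors — the same shape [cluster_compound_sets()] produces.
#'
#' @return Named list of four character vectors of compound names.
#' @export
published_cluster_compounds <- function() {
  path <- system.file("extdata", "pah_cluster_compounds.tsv",
                      package = "breathmap", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  split(tab$compound, tab$cluster)
}
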