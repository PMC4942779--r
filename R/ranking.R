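# Fisher-discriminant-ratio feature ranking for a two-class labelling.

#' Fisher's discriminant ratio of one feature
#'
#' FDR = (mu1 - mu2)^2 / (s1^2 + s2^2) with sample variances (denominator
#' n - 1). A feature with zero pooled variance scores +Inf when the class
#' means differ and 0 when they coincide. The score is non-negative,
#' symmetric under class swap and invariant under affine transforms
#' x -> a x + b (a != 0) of the whole feature.
#'
#' @param values numeric vector of feature values.
#' @param labels vector with exactly two distinct values, each represented
#'   by at least two samples.
#' @return non-negative scalar (possibly \code{Inf}).
#' @export
fisher_discriminant_ratio <- function(values, labels) {
  if (length(values) != length(labels))
    iq_stop("bad-argument", "values and labels lengths differ")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    iq_stop("degenerate-classes",
            sprintf("need exactly two classes, found %d", length(lev)))
  v1 <- values[labels == lev[1L]]
  v2 <- values[labels == lev[2L]]
  if (length(v1) < 2L || length(v2) < 2L)
    iq_stop("degenerate-classes", "each class needs at least two samples")
  num <- (mean(v1) - mean(v2))^2
  den <- stats::var(v1) + stats::var(v2)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Rank all features of a table by Fisher's discriminant ratio
#'
#' Features are ordered by decreasing FDR for the two-class labelling of
#' the chosen histological index; +Inf entries (zero pooled variance with
#' distinct means, an artifact of small cohorts) sort first and carry a
#' flag; ties are broken alphabetically by feature name.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels named list of \code{\link{index_labels}} covering every
#'   sample of the table.
#' @param index_name one of \code{\link{index_names}()}.
#' @return object of class \code{fdr_ranking}: a data frame with columns
#'   \code{rank}, \code{feature}, \code{fdr}, \code{infinite},
#'   \code{family}, \code{roi}, \code{modality}; attribute
#'   \code{class_definition} records (index, level_0, level_alt).
#' @export
rank_features <- function(table, labels, index_name) {
  stopifnot(inherits(table, "feature_table"))
  index_name <- match.arg(index_name, index_names())
  y <- index_label_vector(labels, table$sample_ids, index_name)
  fdr <- vapply(seq_len(ncol(table$values)), function(j)
    fisher_discriminant_ratio(table$values[, j], y), 0)
  feat <- table$feature_names
  ord <- order(-fdr, feat)
  meta <- table$feature_meta
  out <- data.frame(rank = seq_along(ord), feature = feat[ord],
                    fdr = fdr[ord], infinite = is.infinite(fdr[ord]),
                    family = meta$family[ord], roi = meta$roi[ord],
                    modality = meta$modality[ord])
  rownames(out) <- NULL
  lev <- sort(unique(y))
  attr(out, "class_definition") <- list(index = index_name,
                                        level_0 = lev[1L],
                                        level_alt = lev[2L])
  class(out) <- c("fdr_ranking", "data.frame")
  out
}

# Pull one index as an integer vector aligned with sample_ids.
index_label_vector <- function(labels, sample_ids, index_name) {
  if (inherits(labels, "index_labels")) labels <- list(labels)
  miss <- setdiff(sample_ids, names(labels))
  if (length(miss))
    iq_stop("bad-argument",
            paste0("no labels for sample(s): ", paste(miss, collapse = ", ")))
  vapply(labels[sample_ids], `[[`, 0L, index_name)
}

#' Mean FDR by feature family / ROI / modality
#'
#' Aggregates the finite FDR values of a ranking by the chosen metadata
#' tags; +Inf entries are excluded (zero-variance artifacts carry no usable
#' effect-size information). Used to summarise which feature families carry
#' the discriminative signal for a given index.
#'
#' @param ranking an \code{\link{rank_features}} result.
#' @param by metadata columns to group by (subset of
#'   \code{c("family", "roi", "modality")}).
#' @return data frame with the grouping columns, \code{n_features} and
#'   \code{mean_fdr} (0 for groups with no finite entries).
#' @export
family_significance_summary <- function(ranking, by = "family") {
  stopifnot(inherits(ranking, "fdr_ranking"),
            all(by %in% c("family", "roi", "modality")))
  tags <- ranking[by]
  tags[] <- lapply(tags, function(x) ifelse(is.na(x), "n/a", x))
  key <- do.call(paste, c(tags, sep = "\r"))
  groups <- sort(unique(key))
  fin <- is.finite(ranking$fdr)
  mean_fdr <- vapply(groups, function(g) {
    v <- ranking$fdr[fin & key == g]
    if (length(v)) mean(v) else 0
  }, 0)
  n_feat <- vapply(groups, function(g) sum(key == g), 0L)
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- by
  out$n_features <- as.integer(n_feat)
  out$mean_fdr <- unname(mean_fdr)
  rownames(out) <- NULL
  out
}
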