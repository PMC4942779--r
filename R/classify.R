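# Two-class linear discriminant analysis with LD-value thresholding,
# leave-one-out cross-validation and greedy forward feature selection;
# one model per histological index.
#
# Fitting convention: features are z-scored over the training samples
# (re-derived inside every LOO fold to avoid leakage); the pooled
# within-class covariance S_w (denominator n - 2) is ridge-regularised as
# S_w + lambda * (tr(S_w)/d) * I; w = S_w^-1 (mu_alt - mu_0); the decision
# threshold is the projected midpoint of the class means, with the sign
# convention LD(mu_alt) > t. Ties (LD == t) go to level_0.

# Minimal fitter used in the hot LOO loop. X: numeric matrix, y01: 0/1
# integer vector with both classes present and >= 2 samples each.
lda_core <- function(X, y01, lambda) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  i1 <- y01 == 1L
  m0 <- colMeans(Z[!i1, , drop = FALSE])
  m1 <- colMeans(Z[i1, , drop = FALSE])
  A <- sweep(Z[!i1, , drop = FALSE], 2L, m0)
  B <- sweep(Z[i1, , drop = FALSE], 2L, m1)
  Sw <- (crossprod(A) + crossprod(B)) / (nrow(X) - 2L)
  d <- ncol(X)
  tr <- sum(diag(Sw))
  ridge <- if (tr > 0) lambda * tr / d else lambda
  diag(Sw) <- diag(Sw) + ridge
  w <- tryCatch(drop(solve(Sw, m1 - m0)),
                error = function(e) rep(0, d))
  degenerate <- sqrt(sum(w^2)) < 1e-12
  list(w = w, t = sum(w * (m0 + m1)) / 2, center = ctr, scale = scl,
       degenerate = degenerate,
       majority1 = mean(y01) > 0.5)
}

lda_project <- function(core, X) {
  Z <- sweep(sweep(X, 2L, core$center), 2L, core$scale, "/")
  drop(Z %*% core$w)
}

#' Fit a two-class LDA model
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y two-class label vector; the smaller value is taken as
#'   \code{level_0}, the larger as \code{level_alt}.
#' @param lambda relative ridge added to the pooled within-class covariance
#'   (default 1e-3), needed when the feature count approaches the sample
#'   count.
#' @param class_codes optional length-2 vector overriding the class codes.
#' @return object of class \code{lda_model} with elements
#'   \code{feature_names}, \code{w}, \code{t}, \code{class_codes},
#'   \code{lambda}, standardisation constants, and \code{degenerate}
#'   (TRUE when the class means coincide and classification falls back to
#'   the majority class).
#' @export
fit_lda <- function(X, y, lambda = 1e-3, class_codes = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    iq_stop("degenerate-classes",
            sprintf("need exactly two classes, found %d", length(lev)))
  if (min(table(y)) < 2L)
    iq_stop("degenerate-classes", "each class needs at least two samples")
  if (is.null(class_codes)) class_codes <- lev
  core <- lda_core(X, as.integer(y == lev[2L]), lambda)
  if (core$degenerate)
    iq_warn("identical class means: classifier falls back to the majority class")
  structure(c(core,
              list(feature_names = colnames(X), class_codes = class_codes,
                   lambda = lambda)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d feature(s), classes %s/%s, threshold %.4g%s\n",
              length(x$feature_names), x$class_codes[1L], x$class_codes[2L],
              x$t, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Align a feature matrix / table / named vector to the model's features.
align_features <- function(model, x) {
  if (inherits(x, "feature_table")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    iq_stop("feature-mismatch",
            paste0("missing feature(s): ", paste(miss, collapse = ", ")))
  x[, model$feature_names, drop = FALSE]
}

#' Project feature vectors onto the discriminant axis
#'
#' @param model an \code{\link{lda_model}}.
#' @param x feature matrix, \code{\link{feature_table}} or named vector;
#'   aligned to the model by feature name.
#' @return numeric vector of LD values.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  lda_project(model, align_features(model, x))
}

#' Classify feature vectors by LD thresholding
#'
#' A sample is assigned \code{level_alt} iff its LD value exceeds the
#' threshold (ties go to \code{level_0}). A degenerate model returns the
#' majority class of its training data.
#'
#' @inheritParams project
#' @return vector of class codes.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  X <- align_features(model, x)
  if (model$degenerate)
    return(rep(model$class_codes[1L + model$majority1], nrow(X)))
  ld <- lda_project(model, X)
  model$class_codes[1L + (ld > model$t)]
}

#' Leave-one-out cross-validation of a two-class LDA
#'
#' Each sample is predicted by a model fitted on the remaining n - 1
#' (standardisation re-derived per fold). Folds whose training set would
#' leave a class as a singleton are skipped with a warning and counted as
#' errors.
#'
#' @param X numeric matrix (samples x features).
#' @param y two-class labels, n >= 4 with at least two per class.
#' @param feature_subset optional character vector of columns to use.
#' @param lambda ridge parameter, see \code{\link{fit_lda}}.
#' @return list with \code{accuracy} (fraction of correct held-out
#'   predictions), \code{ld} (held-out LD value minus the fold threshold,
#'   per sample; NA for skipped folds), \code{predicted} (class codes) and
#'   \code{correct} (logical).
#' @export
loo_cv <- function(X, y, feature_subset = NULL, lambda = 1e-3) {
  X <- as.matrix(X)
  if (!is.null(feature_subset)) {
    miss <- setdiff(feature_subset, colnames(X))
    if (length(miss))
      iq_stop("feature-mismatch",
              paste0("unknown feature(s): ", paste(miss, collapse = ", ")))
    X <- X[, feature_subset, drop = FALSE]
  }
  n <- nrow(X)
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    iq_stop("degenerate-classes", "need exactly two classes")
  if (n < 4L || min(table(y)) < 2L)
    iq_stop("degenerate-classes",
            "LOO-CV needs n >= 4 with at least two samples per class")
  y01 <- as.integer(y == lev[2L])
  ld <- rep(NA_real_, n)
  pred <- rep(lev[1L], n)
  correct <- logical(n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- y01[-i]
    if (min(sum(ytr == 0L), sum(ytr == 1L)) < 1L) {
      skipped <- skipped + 1L
      next
    }
    core <- suppressWarnings(lda_core(X[-i, , drop = FALSE], ytr, lambda))
    if (core$degenerate) {
      pred[i] <- lev[1L + core$majority1]
      ld[i] <- 0
    } else {
      ldi <- lda_project(core, X[i, , drop = FALSE])
      ld[i] <- ldi - core$t
      pred[i] <- lev[1L + (ldi > core$t)]
    }
    correct[i] <- pred[i] == y[i]
  }
  if (skipped > 0L)
    iq_warn(sprintf("%d LOO fold(s) skipped (singleton training class), counted as errors",
                    skipped))
  list(accuracy = mean(correct), ld = ld, predicted = pred, correct = correct)
}

#' Greedy forward feature selection maximising LOO accuracy
#'
#' Starting from the empty set, each step adds the feature whose inclusion
#' maximises leave-one-out accuracy; ties are broken by larger mean
#' held-out margin |LD - t|, then by FDR rank, then alphabetically. The
#' search stops when no candidate strictly improves the accuracy or when
#' \code{max_features} is reached. Defaults mirror the subset sizes used
#' for the three indices: 10 features for architecture, 20 for chronicity
#' and activity.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels named list of \code{\link{index_labels}}.
#' @param index_name one of \code{\link{index_names}()}.
#' @param max_features cap on the subset size (default by index).
#' @param families_allowed \code{"geometry_plus_irp"} (all features) or
#'   \code{"geometry_only"}.
#' @param lambda ridge parameter for the LDA fits.
#' @return object of class \code{selection_result}: list with
#'   \code{selected_features}, \code{loo_accuracy}, \code{ld} (held-out
#'   margins of the final subset), \code{trace} (data frame: step, feature,
#'   accuracy), \code{model} (final \code{\link{lda_model}} fitted on all
#'   samples), \code{index}, \code{families_allowed}.
#' @export
select_features <- function(table, labels, index_name,
                            max_features = NULL,
                            families_allowed = c("geometry_plus_irp",
                                                 "geometry_only"),
                            lambda = 1e-3) {
  stopifnot(inherits(table, "feature_table"))
  index_name <- match.arg(index_name, index_names())
  families_allowed <- match.arg(families_allowed)
  max_features <- max_features %||%
    (if (index_name == "architecture") 10L else 20L)
  keep <- if (families_allowed == "geometry_only")
    table$feature_meta$family == "geometry" else rep(TRUE, ncol(table$values))
  X <- table$values[, keep, drop = FALSE]
  y <- index_label_vector(labels, table$sample_ids, index_name)
  ranking <- rank_features(table, labels, index_name)
  fdr_pos <- match(colnames(X), ranking$feature)

  selected <- character(0)
  best <- list(accuracy = -Inf, ld = rep(NA_real_, nrow(X)))
  trace <- data.frame(step = integer(0), feature = character(0),
                      accuracy = numeric(0))
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (!length(cand) || length(selected) >= max_features) break
    acc <- margin <- rep(-Inf, length(cand))
    cvs <- vector("list", length(cand))
    for (k in seq_along(cand)) {
      cv <- suppressWarnings(
        loo_cv(X, y, feature_subset = c(selected, cand[k]), lambda = lambda))
      cvs[[k]] <- cv
      acc[k] <- cv$accuracy
      margin[k] <- mean(abs(cv$ld), na.rm = TRUE)
    }
    top <- max(acc)
    if (top <= best$accuracy) break
    tied <- which(acc == top)
    if (length(tied) > 1L)
      tied <- tied[margin[tied] == max(margin[tied])]
    if (length(tied) > 1L)
      tied <- tied[fdr_pos[match(cand[tied], colnames(X))] ==
                     min(fdr_pos[match(cand[tied], colnames(X))])]
    pick <- tied[order(cand[tied])][1L]
    selected <- c(selected, cand[pick])
    best <- cvs[[pick]]
    trace <- rbind(trace, data.frame(step = length(selected),
                                     feature = cand[pick], accuracy = top))
  }
  if (!length(selected)) {
    # no single feature beats -Inf only if there were no candidates at all;
    # with candidates the first step always selects one. Defensive fallback:
    selected <- colnames(X)[1L]
    best <- suppressWarnings(loo_cv(X, y, feature_subset = selected,
                                    lambda = lambda))
  }
  model <- suppressWarnings(
    fit_lda(X[, selected, drop = FALSE], y, lambda = lambda))
  structure(list(selected_features = selected,
                 loo_accuracy = best$accuracy,
                 ld = best$ld, trace = trace, model = model,
                 index = index_name, families_allowed = families_allowed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s (%s): %d feature(s), LOO accuracy %.3f\n",
              x$index, x$families_allowed, length(x$selected_features),
              x$loo_accuracy))
  invisible(x)
}

#' Nested leave-one-out evaluation of the whole selection pipeline
#'
#' The non-nested \code{loo_accuracy} reported by
#' \code{\link{select_features}} is optimistically biased, because the
#' subset is chosen by maximising that very quantity. This mode removes the
#' selection bias: for every held-out sample, the full greedy search is
#' re-run on the remaining n - 1 samples and the held-out sample is
#' predicted by the resulting model. On features that carry no class
#' information the nested accuracy stays at chance level. Off the default
#' path (the headline accuracies use the non-nested estimate), but the
#' right tool for testing whether a feature family truly generalises.
#'
#' @inheritParams select_features
#' @return list with \code{accuracy}, \code{predicted}, \code{correct}.
#' @export
nested_loo_cv <- function(table, labels, index_name,
                          max_features = NULL,
                          families_allowed = c("geometry_plus_irp",
                                               "geometry_only"),
                          lambda = 1e-3) {
  stopifnot(inherits(table, "feature_table"))
  index_name <- match.arg(index_name, index_names())
  families_allowed <- match.arg(families_allowed)
  n <- nrow(table$values)
  y <- index_label_vector(labels, table$sample_ids, index_name)
  pred <- integer(n)
  for (i in seq_len(n)) {
    sub <- table[-i, ]
    sel <- suppressWarnings(
      select_features(sub, labels, index_name, max_features = max_features,
                      families_allowed = families_allowed, lambda = lambda))
    pred[i] <- as.integer(classify(sel$model,
                                   table$values[i, , drop = FALSE]))
  }
  list(accuracy = mean(pred == y), predicted = pred, correct = pred == y)
}

#' Predict the three histological indices for one sample
#'
#' Applies three independently trained two-class LDA models (architecture,
#' chronicity, activity) to one feature row and assembles the result into
#' \code{\link{index_labels}}. Alignment is by feature name, so the
#' prediction is invariant to feature-column order.
#'
#' @param feature_row single-row \code{\link{feature_table}}, matrix or
#'   named vector.
#' @param models named list with one \code{\link{lda_model}} (or
#'   \code{\link{select_features}} result) per entry of
#'   \code{\link{index_names}()}.
#' @return an \code{\link{index_labels}} object.
#' @export
predict_indices <- function(feature_row, models) {
  get_model <- function(m) if (inherits(m, "selection_result")) m$model else m
  lv <- lapply(index_names(), function(ix) {
    m <- get_model(models[[ix]])
    if (is.null(m)) iq_stop("bad-argument", paste0("no model for ", ix))
    as.integer(classify(m, feature_row)[1L])
  })
  index_labels(lv[[1L]], lv[[2L]], lv[[3L]])
}
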