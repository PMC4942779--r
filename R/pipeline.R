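# Pipeline orchestration: simulate -> preprocess -> extract -> rank ->
# train -> report, as a reproducible run over on-disk artifacts. Every
# stage reads only the previous stage's files, so stages can be re-run
# independently.

#' Run configuration
#'
#' @param cohort a \code{\link{cohort_spec}} (synthetic input definition).
#' @param preprocess a \code{\link{preprocess_config}}.
#' @param lambda ridge parameter for the LDA fits.
#' @param max_features optional cap on selected features (default: 10 for
#'   architecture, 20 for chronicity/activity).
#' @param families_allowed \code{"geometry_plus_irp"} or
#'   \code{"geometry_only"}.
#' @param stages stages to execute, in canonical order.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_spec(),
                       preprocess = preprocess_config(),
                       lambda = 1e-3,
                       max_features = NULL,
                       families_allowed = "geometry_plus_irp",
                       stages = c("simulate", "preprocess", "extract",
                                  "rank", "train", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, preprocess = preprocess, lambda = lambda,
                 max_features = max_features,
                 families_allowed = families_allowed, stages = stages),
            class = "run_config")
}

log_line <- function(dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", sep = "", file = file.path(dir, "run.log"), append = TRUE)
  invisible(msg)
}

list_sample_ids <- function(dir) {
  f <- list.files(dir, pattern = "\\.tif$")
  f <- f[!grepl("_(crypts|mucosa)\\.tif$", f)]
  sort(sub("\\.tif$", "", f))
}

read_sample_set <- function(dir, policy = "error") {
  ids <- list_sample_ids(dir)
  lapply(ids, function(sid) {
    list(sample = read_sample(file.path(dir, paste0(sid, ".tif"))),
         roi = read_roi_set(file.path(dir, paste0(sid, "_crypts.tif")),
                            file.path(dir, paste0(sid, "_mucosa.tif")),
                            policy = policy))
  })
}

stage_simulate <- function(config, out_dir) {
  cohort <- generate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "raw"), spec = config$cohort)
  log_line(out_dir, "simulate: wrote ", length(cohort), " sample(s), seed ",
           config$cohort$seed)
  invisible(NULL)
}

stage_preprocess <- function(config, out_dir) {
  src <- file.path(out_dir, "raw")
  dst <- file.path(out_dir, "preprocessed")
  dir.create(dst, showWarnings = FALSE, recursive = TRUE)
  items <- read_sample_set(src)
  for (it in items) {
    pp <- preprocess_sample(it$sample, it$roi, config$preprocess)
    sid <- pp$sample$sample_id
    write_sample(pp$sample, file.path(dst, paste0(sid, ".tif")),
                 grid_tag = "downsampled")
    write_roi_set(pp$roi, file.path(dst, paste0(sid, "_crypts.tif")),
                  file.path(dst, paste0(sid, "_mucosa.tif")))
    for (nm in channel_names())
      log_line(out_dir, sprintf("preprocess %s %s: mean %.4f sd %.4f",
                                sid, nm, mean(pp$sample$channels[[nm]]),
                                stats::sd(pp$sample$channels[[nm]])))
  }
  file.copy(file.path(src, "labels.csv"), file.path(dst, "labels.csv"),
            overwrite = TRUE)
  invisible(NULL)
}

stage_extract <- function(config, out_dir) {
  src <- file.path(out_dir, "preprocessed")
  items <- read_sample_set(src)
  ft <- extract_feature_table(items)
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  log_line(out_dir, "extract: ", nrow(ft$values), " x ", ncol(ft$values),
           " feature table")
  invisible(NULL)
}

stage_rank <- function(config, out_dir) {
  ft <- read_feature_table(file.path(out_dir, "features.csv"))
  labels <- read_labels(file.path(out_dir, "preprocessed", "labels.csv"))
  for (ix in index_names()) {
    rk <- rank_features(ft, labels, ix)
    utils::write.csv(as.data.frame(rk),
                     file.path(out_dir, paste0("ranking_", ix, ".csv")),
                     row.names = FALSE)
    fam <- family_significance_summary(rk, by = c("family", "roi"))
    utils::write.csv(fam,
                     file.path(out_dir, paste0("family_summary_", ix, ".csv")),
                     row.names = FALSE)
  }
  log_line(out_dir, "rank: wrote rankings for ",
           paste(index_names(), collapse = ", "))
  invisible(NULL)
}

stage_train <- function(config, out_dir) {
  ft <- read_feature_table(file.path(out_dir, "features.csv"))
  labels <- read_labels(file.path(out_dir, "preprocessed", "labels.csv"))
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  ld_rows <- list()
  for (ix in index_names()) {
    sel <- select_features(ft, labels, ix,
                           max_features = config$max_features,
                           families_allowed = config$families_allowed,
                           lambda = config$lambda)
    write_lda_model(sel$model,
                    file.path(out_dir, "models", paste0("model_", ix, ".json")))
    utils::write.csv(sel$trace,
                     file.path(out_dir, paste0("selection_", ix, ".csv")),
                     row.names = FALSE)
    truth <- index_label_vector(labels, ft$sample_ids, ix)
    cv <- suppressWarnings(loo_cv(ft$values, truth,
                                  feature_subset = sel$selected_features,
                                  lambda = config$lambda))
    ld_rows[[ix]] <- data.frame(sample_id = ft$sample_ids, index = ix,
                                truth = truth, predicted = cv$predicted,
                                ld_margin = cv$ld,
                                loo_accuracy = cv$accuracy)
    log_line(out_dir, sprintf("train %s: %d feature(s), LOO accuracy %.3f",
                              ix, length(sel$selected_features), cv$accuracy))
  }
  utils::write.csv(do.call(rbind, c(ld_rows, make.row.names = FALSE)),
                   file.path(out_dir, "ld_values.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Serialise / load a fitted LDA model as JSON
#'
#' @param model an \code{\link{lda_model}}.
#' @param path JSON file path.
#' @return \code{read_lda_model}: an \code{\link{lda_model}}.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  if (!file.exists(path)) iq_stop("file-missing", paste0("no such file: ", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$degenerate <- as.logical(m$degenerate)
  m$majority1 <- as.logical(m$majority1)
  structure(m, class = "lda_model")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in canonical order, writing all artifacts
#' (images, masks, labels, feature table, rankings, models, LD values, log,
#' report) under \code{out_dir}. Stage failures abort with a stage-tagged
#' error; artifacts of completed stages are retained.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return the run report, invisibly (see \code{\link{make_report}}).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"),
                   file.path(out_dir, "run_config.yaml"))
  order_ <- c("simulate", "preprocess", "extract", "rank", "train", "report")
  report <- NULL
  for (st in intersect(order_, config$stages)) {
    res <- tryCatch({
      switch(st,
             simulate = stage_simulate(config, out_dir),
             preprocess = stage_preprocess(config, out_dir),
             extract = stage_extract(config, out_dir),
             rank = stage_rank(config, out_dir),
             train = stage_train(config, out_dir),
             report = {report <- make_report(out_dir); NULL})
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      log_line(out_dir, "stage ", st, " FAILED: ", conditionMessage(res))
      iq_stop("stage-failure",
              sprintf("stage '%s' failed: %s", st, conditionMessage(res)))
    }
  }
  invisible(report)
}

fmt_table <- function(df, digits = 4) {
  if (!nrow(df)) return(character(0))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Assemble the run report from saved artifacts
#'
#' Renders \code{report.md} deterministically from the CSV artifacts of a
#' completed (or partial) run: cohort composition, the top-10 FDR ranking
#' per index, the family significance summary, per-class LD-value quartiles
#' (boxplot data) and LOO confusion counts.
#'
#' @param out_dir directory of a pipeline run.
#' @return character vector of report lines (also written to
#'   \code{report.md}), invisibly.
#' @export
make_report <- function(out_dir) {
  need <- file.path(out_dir, "features.csv")
  if (!file.exists(need))
    iq_stop("missing-artifact", paste0("missing artifact: ", need))
  lines <- c("# Pipeline run report", "")
  lab_file <- file.path(out_dir, "preprocessed", "labels.csv")
  if (file.exists(lab_file)) {
    lab <- utils::read.csv(lab_file)
    lines <- c(lines,
               sprintf("Cohort: %d sample(s); architecture 2: %d; chronicity 2: %d; activity 1: %d.",
                       nrow(lab), sum(lab$architecture == 2),
                       sum(lab$chronicity == 2), sum(lab$activity == 1)), "")
  }
  for (ix in index_names()) {
    rf <- file.path(out_dir, paste0("ranking_", ix, ".csv"))
    if (!file.exists(rf)) next
    rk <- utils::read.csv(rf)
    lines <- c(lines, paste0("## Feature ranking: ", ix), "")
    if (!nrow(rk)) {
      lines <- c(lines, "no features ranked", "")
    } else {
      top <- utils::head(rk[, c("rank", "feature", "fdr", "family")], 10L)
      lines <- c(lines, fmt_table(top), "")
      ff <- file.path(out_dir, paste0("family_summary_", ix, ".csv"))
      if (file.exists(ff))
        lines <- c(lines, "Family trends (mean finite FDR):", "",
                   fmt_table(utils::read.csv(ff)), "")
    }
  }
  ld_file <- file.path(out_dir, "ld_values.csv")
  if (file.exists(ld_file)) {
    ld <- utils::read.csv(ld_file)
    for (ix in unique(ld$index)) {
      d <- ld[ld$index == ix, ]
      lines <- c(lines, paste0("## Classification: ", ix), "",
                 sprintf("LOO accuracy: %.3f", d$loo_accuracy[1L]), "")
      qs <- do.call(rbind, lapply(split(d$ld_margin, d$truth), function(v)
        round(stats::quantile(v, c(0, .25, .5, .75, 1), na.rm = TRUE), 4)))
      qdf <- data.frame(class = rownames(qs), qs, check.names = FALSE)
      lines <- c(lines, "Held-out LD margin quartiles by true class:", "",
                 fmt_table(qdf), "")
      conf <- as.data.frame(table(truth = d$truth, predicted = d$predicted))
      lines <- c(lines, "Confusion counts (LOO):", "", fmt_table(conf), "")
    }
  }
  lines <- unname(lines)
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(lines)
}
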