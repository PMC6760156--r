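#' Read a long-format elemental series CSV
#'
#' Expects header `subject_id,element,day,ratio`; lines beginning with `#`
#' (provenance comments written by this package) are skipped.  Rows are
#' grouped by subject and element and sorted by day.  Duplicate
#' (subject, element, day) rows and negative ratios are rejected with the
#' offending line number.
#'
#' @param path CSV file path.
#' @return Long data frame `subject_id`, `element`, `day`, `ratio`.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "#"))
  if (!length(body_at)) stop(sprintf("%s: no header line", path), call. = FALSE)
  header <- lines[body_at[1]]
  if (trimws(header) != "subject_id,element,day,ratio") {
    stop(sprintf("%s:%d: malformed header, expected 'subject_id,element,day,ratio'",
                 path, body_at[1]), call. = FALSE)
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric", "numeric"))
  if (nrow(d) == 0L) return(d)
  # map data rows back to file line numbers for error messages
  line_no <- body_at[1] + seq_len(nrow(d))
  bad <- which(!is.finite(d$day) | !is.finite(d$ratio))
  if (length(bad)) stop(sprintf("%s:%d: malformed row", path, line_no[bad[1]]), call. = FALSE)
  neg <- which(d$ratio < 0)
  if (length(neg)) {
    stop(sprintf("%s:%d: negative ratio (%g)", path, line_no[neg[1]], d$ratio[neg[1]]),
         call. = FALSE)
  }
  dup <- which(duplicated(d[c("subject_id", "element", "day")]))
  if (length(dup)) {
    stop(sprintf("%s:%d: duplicate (subject, element, day) row", path, line_no[dup[1]]),
         call. = FALSE)
  }
  d[order(d$subject_id, d$element, d$day), , drop = FALSE]
}

provenance_header <- function(seed, hash) {
  sprintf("# toothrqa seed=%s config=%s", as.character(seed), hash)
}

write_stamped <- function(df, path, seed, hash, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
}

#' Write series / subject tables with a provenance comment header
#'
#' @param df Table to write.
#' @param path Output path.
#' @param seed,hash Seed and config hash stamped in the `#` header line.
#' @export
write_series_csv <- function(df, path, seed = NA, hash = "none") {
  write_stamped(df[c("subject_id", "element", "day", "ratio")], path, seed, hash)
}

#' @rdname write_series_csv
#' @export
write_subjects_csv <- function(df, path, seed = NA, hash = "none") {
  cols <- c("subject_id", "pair_id", "zygosity", "sex", "gestational_days",
            "birth_weight", "diagnosis", "iq")
  write_stamped(df[intersect(cols, names(df))], path, seed, hash)
}

#' Read a subject metadata CSV
#'
#' @param path CSV with header `subject_id,pair_id,zygosity,sex,
#'   gestational_days,birth_weight,diagnosis,iq` (comment lines `#` skipped).
#' @return Subject data frame.
#' @export
read_subjects_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "pair_id", "zygosity", "sex", "gestational_days",
            "birth_weight", "diagnosis")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!d$diagnosis %in% c("TD", "ADHD", "ASD", "COMORBID"))
  if (length(bad)) {
    stop(sprintf("%s: unknown diagnosis '%s' (row %d)", path, d$diagnosis[bad[1]], bad[1]),
         call. = FALSE)
  }
  if (any(d$gestational_days <= 0) || any(d$birth_weight <= 0)) {
    stop(sprintf("%s: gestational_days and birth_weight must be positive", path),
         call. = FALSE)
  }
  d
}

#' Export a recurrence matrix as a plain-text 0/1 grid
#'
#' @param x An `rqa_matrix`.
#' @param path Output path.
#' @export
write_recurrence_grid <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# toothrqa recurrence grid kind=%s eps=%g", x$kind, x$eps), con)
  utils::write.table(x$R + 0L, con, sep = " ", row.names = FALSE, col.names = FALSE)
}

#' Assemble a full run configuration
#'
#' @param cohort A [cohort_config()]; ignored when `series_csv` /
#'   `subjects_csv` point at input files to analyse instead of simulating.
#' @param embedding An [embedding_params()].
#' @param pathways Pathway data frame (see [pathway_spec()]).
#' @param outlier_k,outlier_mode,alpha Scan settings (see
#'   [run_feature_scan()]); `alpha` is the reporting significance level.
#' @param series_csv,subjects_csv Optional input files; when both are set the
#'   simulate stage is skipped.
#' @param seed Integer master seed, recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), embedding = embedding_params(),
                       pathways = default_pathways(), outlier_k = 2,
                       outlier_mode = "auto", alpha = 0.05,
                       series_csv = NULL, subjects_csv = NULL, seed = 1L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, embedding = embedding, pathways = pathways,
                 outlier_k = outlier_k, outlier_mode = outlier_mode,
                 alpha = alpha, series_csv = series_csv,
                 subjects_csv = subjects_csv, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Recognised top-level keys: `seed`, `cohort` (fields of [cohort_config()];
#' `base_params` nests [signal_params()] fields), `embedding` (fields of
#' [embedding_params()]), `pathways` (`singles`, `zinc_partners`), `stats`
#' (`outlier_k`, `outlier_mode`, `alpha`), `inputs` (`series_csv`,
#' `subjects_csv`).  Omitted keys take package defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  coh <- y$cohort %||% list()
  if (!is.null(coh$base_params)) coh$base_params <- do.call(signal_params, coh$base_params)
  if (!is.null(coh$group_sizes)) coh$group_sizes <- unlist(coh$group_sizes)
  coh$seed <- seed
  cohort <- do.call(cohort_config, coh)
  embedding <- do.call(embedding_params, y$embedding %||% list())
  pathways <- if (is.null(y$pathways)) default_pathways() else {
    pathway_spec(singles = unlist(y$pathways$singles) %||% character(),
                 zinc_partners = unlist(y$pathways$zinc_partners) %||% character())
  }
  st <- y$stats %||% list()
  run_config(cohort = cohort, embedding = embedding, pathways = pathways,
             outlier_k = st$outlier_k %||% 2, outlier_mode = st$outlier_mode %||% "auto",
             alpha = st$alpha %||% 0.05,
             series_csv = y$inputs$series_csv, subjects_csv = y$inputs$subjects_csv,
             seed = seed)
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Chains simulate (or load) -> feature table -> mixed-model scan ->
#' PCA / LDA, writing every table with a provenance header (`# toothrqa
#' seed=... config=...`), a structured log of exclusions and warnings, and a
#' short human-readable summary.  Identical configurations produce identical
#' artifacts.
#'
#' @param config A `run_config` (see [run_config()], [read_run_config()]).
#' @param output_dir Directory for artifacts (created if needed).
#' @return Invisibly, a list with the in-memory results (`subjects`,
#'   `series`, `features`, `scan`, `pca`, `component_tests`, `lda`,
#'   `loadings`) and the paths written.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "run_config")) stop("config must be a run_config", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$series_csv) && !is.null(config$subjects_csv)) {
    note("input", sprintf("loading series from %s", config$series_csv))
    series <- stage("load", read_series_csv(config$series_csv))
    subjects <- stage("load", read_subjects_csv(config$subjects_csv))
  } else {
    note("simulate", sprintf("generating cohort, seed=%d", seed))
    sim <- stage("simulate", generate_cohort(config$cohort))
    series <- sim$series
    subjects <- sim$subjects
  }

  note("features", sprintf("%d subjects x %d pathways", nrow(subjects), nrow(config$pathways)))
  features <- stage("features", compute_feature_table(series, subjects,
                                                      config$pathways, config$embedding))
  flog <- attr(features, "log")
  if (nrow(flog)) {
    note("features", sprintf("%d missing cell group(s):", nrow(flog)))
    log_lines <- c(log_lines, sprintf("[features]   %s/%s: %s",
                                      flog$subject_id, flog$pathway, flog$reason))
  }

  scan <- stage("scan", run_feature_scan(features, subjects, outlier_k = config$outlier_k,
                                         outlier_mode = config$outlier_mode))
  note("scan", sprintf("%d features, %d significant at FDR %.2f",
                       nrow(scan), sum(scan$p_fdr <= config$alpha, na.rm = TRUE),
                       config$alpha))

  dimred <- stage("dimred", withCallingHandlers({
    pca <- pca_fit(features)
    ct <- component_group_tests(pca, subjects)
    lda <- lda_fit(features, subjects)
    list(pca = pca, ct = ct, lda = lda, loadings = lda_loadings(lda, features))
  }, warning = function(w) {
    note("dimred", conditionMessage(w))
    invokeRestart("muffleWarning")
  }))
  note("dimred", sprintf("PCA retained %d components (%.1f%% variance); LDA on %d subjects, %d excluded",
                         length(dimred$pca$retained),
                         100 * dimred$pca$cum_share[max(dimred$pca$retained)],
                         nrow(dimred$lda$scores), length(dimred$lda$excluded_subjects)))

  p <- function(f) file.path(output_dir, f)
  write_subjects_csv(subjects, p("subjects.csv"), seed, hash)
  write_series_csv(series, p("series.csv"), seed, hash)
  write_stamped(features, p("features.csv"), seed, hash)
  write_stamped(scan, p("scan.tsv"), seed, hash, sep = "\t")
  write_stamped(data.frame(component = seq_along(dimred$pca$eigenvalues),
                           eigenvalue = dimred$pca$eigenvalues,
                           cum_share = dimred$pca$cum_share,
                           retained = seq_along(dimred$pca$eigenvalues) %in% dimred$pca$retained),
                p("pca_eigenvalues.csv"), seed, hash)
  write_stamped(data.frame(subject_id = rownames(dimred$pca$scores),
                           dimred$pca$scores[, dimred$pca$retained, drop = FALSE]),
                p("pca_scores.csv"), seed, hash)
  write_stamped(dimred$ct, p("component_tests.tsv"), seed, hash, sep = "\t")
  write_stamped(data.frame(subject_id = rownames(dimred$lda$scores), dimred$lda$scores),
                p("lda_scores.csv"), seed, hash)
  write_stamped(data.frame(feature = rownames(dimred$loadings), dimred$loadings),
                p("lda_loadings.csv"), seed, hash)
  writeLines(c(provenance_header(seed, hash), log_lines), p("run_log.txt"))

  sig <- scan[!is.na(scan$p_fdr) & scan$p_fdr <= config$alpha, ]
  summary_lines <- c(
    provenance_header(seed, hash),
    sprintf("subjects: %d  series: %d  features: %d", nrow(subjects),
            nrow(unique(series[c("subject_id", "element")])), ncol(features) - 1L),
    sprintf("ADHD effects significant at FDR <= %.2f: %d", config$alpha, nrow(sig)),
    if (nrow(sig)) sprintf("  %s beta=%.4f p_fdr=%.4f", sig$feature, sig$beta_adhd, sig$p_fdr),
    sprintf("PCA: %d retained components, %.2f%% cumulative variance",
            length(dimred$pca$retained), 100 * dimred$pca$cum_share[max(dimred$pca$retained)]),
    sprintf("LDA: %d axes over %d subjects", ncol(dimred$lda$scores), nrow(dimred$lda$scores)))
  writeLines(summary_lines, p("summary.txt"))

  invisible(list(subjects = subjects, series = series, features = features,
                 scan = scan, pca = dimred$pca, component_tests = dimred$ct,
                 lda = dimred$lda, loadings = dimred$loadings,
                 output_dir = output_dir, hash = hash))
}
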