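#' Exclude values beyond k standard deviations
#'
#' Single-pass screen used before modelling to meet normality assumptions:
#' values farther than `k` standard deviations from the mean (both computed
#' over the non-missing input) are set to missing.  No iteration — the mean
#' and SD are not recomputed after exclusion.
#'
#' @param values Numeric vector, possibly with `NA`s; at least 3 non-missing.
#' @param k Threshold in SD units (default 2).
#' @return `values` with outliers replaced by `NA`.
#' @export
exclude_outliers <- function(values, k = 2) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("insufficient data: need at least 3 non-missing values", call. = FALSE)
  mu <- mean(values[ok])
  s <- stats::sd(values[ok])
  out <- ok & abs(values - mu) > k * s
  values[out] <- NA_real_
  values
}

adhd_indicator <- function(diagnosis) as.integer(diagnosis %in% c("ADHD", "COMORBID"))
asd_indicator <- function(diagnosis) as.integer(diagnosis %in% c("ASD", "COMORBID"))

#' Twin-clustered linear mixed model for one feature
#'
#' Fits, by REML,
#' `y ~ adhd + sex + gestational_days + birth_weight + asd + (1 | pair_id)`
#' where `adhd` and `asd` are non-exclusive indicators (a comorbid subject is
#' 1 on both), the pair-level random intercept absorbs shared
#' genetic/environmental variance within a twin pair, and singletons form
#' singleton clusters.  The ADHD effect is tested with a Wald z statistic.
#'
#' @param feature Numeric vector of feature values, aligned with `subjects`
#'   rows (or named by `subject_id`).
#' @param subjects Subject table with `subject_id`, `pair_id`, `sex`,
#'   `gestational_days`, `birth_weight`, `diagnosis`.
#' @param id Optional feature identifier carried into the result.
#' @return A list of class `mixed_model_result`: `id`, `beta_adhd`, `se`,
#'   `p_raw`, `covariate_betas` (sex/gestational_days/birth_weight/asd),
#'   `n_used`, `converged`.
#' @export
fit_twin_mixed_model <- function(feature, subjects, id = NA_character_) {
  if (!is.null(names(feature))) feature <- feature[subjects$subject_id]
  if (length(feature) != nrow(subjects)) {
    stop("feature must align with the subject table", call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(feature),
    adhd = adhd_indicator(subjects$diagnosis),
    asd = asd_indicator(subjects$diagnosis),
    sex = factor(subjects$sex, levels = c("F", "M")),
    gestational_days = subjects$gestational_days,
    birth_weight = subjects$birth_weight,
    pair_id = subjects$pair_id)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_pairs_complete <- sum(table(d$pair_id) >= 2L)
  if (n_pairs_complete < 2L) stop("insufficient data: fewer than 2 complete pairs", call. = FALSE)
  if (length(unique(d$y)) < 2L || length(unique(d$adhd)) < 2L) {
    stop("inestimable contrast: constant response or no ADHD variation", call. = FALSE)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(
      y ~ adhd + sex + gestational_days + birth_weight + asd + (1 | pair_id),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b["adhd"] / se["adhd"]
  structure(list(
    id = id,
    beta_adhd = unname(b["adhd"]),
    se = unname(se["adhd"]),
    p_raw = max(unname(2 * stats::pnorm(-abs(z))), .Machine$double.xmin),
    covariate_betas = c(sex = unname(b["sexM"]),
                        gestational_days = unname(b["gestational_days"]),
                        birth_weight = unname(b["birth_weight"]),
                        asd = unname(b["asd"])),
    n_used = nrow(d),
    converged = converged), class = "mixed_model_result")
}

#' Benjamini-Hochberg FDR, stratified by pathway
#'
#' Applies the BH step-up procedure independently within each stratum (in the
#' feature scan, each pathway's four measures form one stratum), so a
#' pathway's adjustment is not diluted by tests from other pathways.
#'
#' @param p_raw Named numeric vector of raw p-values in (0, 1\].
#' @param strata Character vector (or named, matching `p_raw` names) giving
#'   each feature's stratum label.
#' @return Named numeric vector of adjusted p-values, same order as `p_raw`.
#' @export
fdr_by_stratum <- function(p_raw, strata) {
  if (length(strata) != length(p_raw)) {
    stop("validation error: strata must match p_raw in length", call. = FALSE)
  }
  if (anyNA(strata)) stop("validation error: unknown stratum label (NA)", call. = FALSE)
  if (any(!is.na(p_raw) & (p_raw <= 0 | p_raw > 1))) {
    stop("validation error: p-values must lie in (0, 1]", call. = FALSE)
  }
  adj <- rep(NA_real_, length(p_raw))
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(p_raw))
    if (length(idx)) adj[idx] <- stats::p.adjust(p_raw[idx], method = "BH")
  }
  names(adj) <- names(p_raw)
  adj
}

#' Per-feature mixed-model scan with stratified FDR
#'
#' For every feature column: screens outliers (see `outlier_mode`), fits the
#' twin-clustered mixed model of [fit_twin_mixed_model()], and collects the
#' ADHD effect; raw p-values are then Benjamini-Hochberg adjusted within each
#' pathway stratum.  Per-feature failures (constant columns, too little data)
#' are contained as flagged rows and the scan continues.
#'
#' @param table Feature table from [compute_feature_table()].
#' @param subjects Subject table.
#' @param outlier_k SD threshold for [exclude_outliers()].
#' @param outlier_mode `"auto"` screens only columns that fail a
#'   Shapiro-Wilk normality check at `alpha_normality`; `"all"` screens every
#'   column; `"none"` disables screening.
#' @param alpha_normality Shapiro-Wilk level used by `"auto"`.
#' @return A data frame, one row per feature column: `feature`, `pathway`,
#'   `measure`, `beta_adhd`, `se`, `p_raw`, `p_fdr`, covariate betas,
#'   `n_used`, `converged`, `error`.
#' @export
run_feature_scan <- function(table, subjects, outlier_k = 2,
                             outlier_mode = c("auto", "all", "none"),
                             alpha_normality = 0.05) {
  outlier_mode <- match.arg(outlier_mode)
  feats <- feature_columns(table)
  if (!length(feats)) stop("feature table has no feature columns", call. = FALSE)
  meta <- split_feature_name(feats)
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    y <- stats::setNames(table[[feats[i]]], table$subject_id)
    res <- tryCatch({
      screen <- switch(outlier_mode,
        all = TRUE,
        none = FALSE,
        auto = {
          v <- y[!is.na(y)]
          length(unique(v)) >= 3L && length(v) >= 3L && length(v) <= 5000L &&
            stats::shapiro.test(v)$p.value < alpha_normality
        })
      if (screen) y <- exclude_outliers(y, k = outlier_k)
      fit_twin_mixed_model(y, subjects, id = feats[i])
    }, error = function(e) conditionMessage(e))
    rows[[i]] <- if (is.character(res)) {
      data.frame(feature = feats[i], pathway = meta$pathway[i], measure = meta$measure[i],
                 beta_adhd = NA_real_, se = NA_real_, p_raw = NA_real_,
                 beta_sex = NA_real_, beta_gestational_days = NA_real_,
                 beta_birth_weight = NA_real_, beta_asd = NA_real_,
                 n_used = 0L, converged = FALSE, error = res,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(feature = feats[i], pathway = meta$pathway[i], measure = meta$measure[i],
                 beta_adhd = res$beta_adhd, se = res$se, p_raw = res$p_raw,
                 beta_sex = res$covariate_betas[["sex"]],
                 beta_gestational_days = res$covariate_betas[["gestational_days"]],
                 beta_birth_weight = res$covariate_betas[["birth_weight"]],
                 beta_asd = res$covariate_betas[["asd"]],
                 n_used = res$n_used, converged = res$converged, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_by_stratum(out$p_raw, out$pathway)
  out[c("feature", "pathway", "measure", "beta_adhd", "se", "p_raw", "p_fdr",
        "beta_sex", "beta_gestational_days", "beta_birth_weight", "beta_asd",
        "n_used", "converged", "error")]
}
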