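#' Signal parameters for a synthetic elemental tooth profile
#'
#' Describes the generative model for one element's metal:Ca ratio signal as
#' sampled by laser-ablation ICP-MS along a tooth's growth axis: a sinusoidal
#' metabolic cycle whose phase diffuses (a Brownian phase walk) and whose
#' measurement noise is autocorrelated (AR(1)).  A single knob, `regularity`,
#' controls how strictly periodic the signal is: at 1 the phase walk has zero
#' step and the cycle is perfectly periodic; lower values both accelerate the
#' phase diffusion and inflate the noise.
#'
#' @param base_level Baseline metal:Ca ratio (arbitrary ratio units).
#' @param amplitude Amplitude of the metabolic cycle, same units as
#'   `base_level`.
#' @param period_days Cycle period in days.
#' @param regularity Real in \[0, 1\]; 1 = perfectly periodic.
#' @param phase_jitter_sd Phase-walk step scale, radians per square-root day;
#'   the effective step standard deviation over a sampling interval `dt` is
#'   `phase_jitter_sd * (1 - regularity) * sqrt(dt)`.
#' @param noise_sd AR(1) innovation scale in ratio units; the effective
#'   innovation standard deviation is `noise_sd * (2 - regularity)`.
#' @param ar_coeff AR(1) coefficient of the noise, in \[0, 1).
#' @param n_points_mean Mean number of sampling locations along the tooth;
#'   the realised count is Poisson with this mean, truncated below at 20.
#' @param day_min,day_max Sampling span in days relative to birth (negative =
#'   prenatal).
#' @param log_scale If `TRUE` the sinusoid-plus-noise signal is exponentiated
#'   (multiplicative, log-normal-like marginals) instead of used additively.
#'
#' @return An object of class `signal_params` (a validated list).
#' @export
signal_params <- function(base_level = 1,
                          amplitude = 0.4,
                          period_days = 15,
                          regularity = 0.85,
                          phase_jitter_sd = 0.5,
                          noise_sd = 0.12,
                          ar_coeff = 0.3,
                          n_points_mean = 152,
                          day_min = -120,
                          day_max = 200,
                          log_scale = FALSE) {
  p <- list(base_level = base_level, amplitude = amplitude,
            period_days = period_days, regularity = regularity,
            phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
            ar_coeff = ar_coeff, n_points_mean = n_points_mean,
            day_min = day_min, day_max = day_max, log_scale = isTRUE(log_scale))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$base_level) || p$base_level < 0) stop_field("base_level", "must be a nonnegative number")
  if (!num1(p$amplitude) || p$amplitude < 0) stop_field("amplitude", "must be a nonnegative number")
  if (!num1(p$period_days) || p$period_days <= 0) stop_field("period_days", "must be positive")
  if (!num1(p$regularity) || p$regularity < 0 || p$regularity > 1) stop_field("regularity", "must lie in [0, 1]")
  if (!num1(p$phase_jitter_sd) || p$phase_jitter_sd < 0) stop_field("phase_jitter_sd", "must be nonnegative")
  if (!num1(p$noise_sd) || p$noise_sd < 0) stop_field("noise_sd", "must be nonnegative")
  if (!num1(p$ar_coeff) || p$ar_coeff < 0 || p$ar_coeff >= 1) stop_field("ar_coeff", "must lie in [0, 1)")
  if (!num1(p$n_points_mean) || p$n_points_mean < 2) stop_field("n_points_mean", "must be at least 2")
  if (!num1(p$day_min) || !num1(p$day_max) || !(p$day_min < 0 && 0 < p$day_max)) {
    stop_field("day_min/day_max", "must satisfy day_min < 0 < day_max")
  }
  structure(p, class = "signal_params")
}

#' Generate one synthetic elemental time-series
#'
#' Samples one tooth profile under the model in [signal_params()]:
#' `value(t) = base_level * subject_factor + amplitude * sin(2*pi*t/period +
#' phi(t)) + eta(t)` with `phi` a Brownian phase walk (plus a random initial
#' phase) and `eta` AR(1) noise; values are clipped at zero, as metal:Ca
#' ratios are nonnegative.  Sampling days are uniformly spaced over
#' `[day_min, day_max]`; the number of points is Poisson around
#' `n_points_mean`, truncated below at 20.  Output is deterministic given
#' `rng_seed`.
#'
#' @param params A [signal_params()] object.
#' @param subject_factor Multiplier on `base_level` encoding subject-level
#'   exposure differences.
#' @param rng_seed Integer seed; the caller's RNG state is untouched.
#' @param subject_id,element Identifiers attached to the returned series.
#'
#' @return An `element_series` object: a list with `subject_id`, `element`,
#'   `times` (days relative to birth, strictly increasing) and `values`
#'   (nonnegative ratios).
#' @export
generate_element_series <- function(params, subject_factor = 1, rng_seed = 1L,
                                    subject_id = NA_character_,
                                    element = NA_character_) {
  if (!inherits(params, "signal_params")) params <- do.call(signal_params, params)
  if (!is.numeric(subject_factor) || length(subject_factor) != 1L ||
      !is.finite(subject_factor) || subject_factor <= 0) {
    stop_field("subject_factor", "must be a positive number")
  }
  with_seed(rng_seed, {
    n <- max(20L, stats::rpois(1L, params$n_points_mean))
    times <- seq(params$day_min, params$day_max, length.out = n)
    dt <- (params$day_max - params$day_min) / (n - 1)
    step_sd <- params$phase_jitter_sd * (1 - params$regularity) * sqrt(dt)
    phi0 <- stats::runif(1L, 0, 2 * pi)
    phi <- cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd)))
    innov_sd <- params$noise_sd * (2 - params$regularity)
    eta <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    filter = params$ar_coeff,
                                    method = "recursive"))
    cyc <- params$amplitude * sin(2 * pi * times / params$period_days + phi0 + phi)
    values <- if (params$log_scale) {
      params$base_level * subject_factor * exp(cyc + eta)
    } else {
      params$base_level * subject_factor + cyc + eta
    }
    new_element_series(subject_id, element, times, pmax(values, 0))
  })
}

new_element_series <- function(subject_id, element, times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2,
            !is.unsorted(times, strictly = TRUE), all(values >= 0))
  structure(list(subject_id = subject_id, element = element,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "element_series")
}

#' @method print element_series
#' @export
print.element_series <- function(x, ...) {
  cat(sprintf("<element_series> %s / %s: %d points, days %.1f..%.1f\n",
              x$subject_id, x$element, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Default per-pathway regularity shifts
#'
#' Diagnosis-specific deficits in cycle regularity, keyed by
#' `diagnosis -> element (or "Zn-<partner>" pair label) -> shift`.  Defaults
#' reduce regularity by 0.2 in Co, Pb, V and Cu for ADHD, and in Zn and the
#' zinc-pair pathways for ASD and the comorbid phenotype (which also carries
#' the ADHD deficits).  Pair-label shifts are applied to the partner
#' element's series, so the cross-recurrence with zinc degrades without
#' touching zinc itself.
#'
#' @param shift Magnitude of the regularity reduction (negative shift).
#' @return Nested named list usable as `pathway_effects` in [cohort_config()].
#' @export
default_pathway_effects <- function(shift = -0.2) {
  adhd <- list(Co = shift, Pb = shift, V = shift, Cu = shift)
  asd <- list(Zn = shift, `Zn-Cu` = shift, `Zn-Pb` = shift, `Zn-Sn` = shift)
  list(ADHD = adhd, ASD = asd, COMORBID = c(adhd, asd))
}

#' Cohort configuration for the synthetic twin generator
#'
#' @param n_pairs Number of complete twin pairs.
#' @param n_triplets Number of triplet groups (each contributes 3 subjects).
#' @param singleton_count Twins whose co-twin did not donate a tooth.
#' @param group_sizes Named counts over diagnoses `TD`, `ADHD`, `ASD`,
#'   `COMORBID`; must sum to the total subject count.  Defaults mirror a
#'   74-subject discordant-twin cohort (41/13/8/12).
#' @param elements Chemical symbols to simulate for every subject.
#' @param pathway_effects Nested list `diagnosis -> element-or-pair -> shift`
#'   added to that subject's regularity for that element (pair labels shift
#'   the partner element); see [default_pathway_effects()].
#' @param twin_correlation Weight in \[0, 1\] mixing the pair-level and
#'   individual latent factors for monozygotic pairs; dizygotic pairs use
#'   half of it.
#' @param base_params [signal_params()] shared by all subjects before
#'   subject- and diagnosis-level perturbation.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 30L,
                          n_triplets = 1L,
                          singleton_count = 11L,
                          group_sizes = c(TD = 41L, ADHD = 13L, ASD = 8L, COMORBID = 12L),
                          elements = c("Zn", "Cu", "Pb", "Co", "V", "Li", "Sn", "Mn", "Ca"),
                          pathway_effects = default_pathway_effects(),
                          twin_correlation = 0.7,
                          base_params = signal_params(),
                          seed = 1L) {
  cnt <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
  if (!cnt(n_pairs)) stop_field("n_pairs", "must be a nonnegative integer")
  if (!cnt(n_triplets)) stop_field("n_triplets", "must be a nonnegative integer")
  if (!cnt(singleton_count)) stop_field("singleton_count", "must be a nonnegative integer")
  total <- 2L * n_pairs + 3L * n_triplets + singleton_count
  if (total < 1L) stop_field("n_pairs", "cohort must contain at least one subject")
  labels <- c("TD", "ADHD", "ASD", "COMORBID")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% labels)) {
    stop_field("group_sizes", "names must be among TD, ADHD, ASD, COMORBID")
  }
  gs <- stats::setNames(rep(0L, 4L), labels)
  gs[names(group_sizes)] <- as.integer(group_sizes)
  if (any(gs < 0)) stop_field("group_sizes", "counts must be nonnegative")
  if (sum(gs) != total) {
    stop_field("group_sizes", sprintf(
      "counts sum to %d but the pair/triplet/singleton structure implies %d subjects",
      sum(gs), total))
  }
  if (!is.character(elements) || length(elements) < 1L || anyDuplicated(elements)) {
    stop_field("elements", "must be a non-empty set of distinct symbols")
  }
  for (dx in names(pathway_effects)) {
    if (!dx %in% labels) stop_field("pathway_effects", sprintf("unknown diagnosis '%s'", dx))
    for (key in names(pathway_effects[[dx]])) {
      el <- sub("^Zn-", "", key)
      if (!el %in% elements) {
        stop_field("pathway_effects", sprintf("'%s' refers to element '%s' not in elements", key, el))
      }
    }
  }
  if (!is.numeric(twin_correlation) || twin_correlation < 0 || twin_correlation > 1) {
    stop_field("twin_correlation", "must lie in [0, 1]")
  }
  if (!inherits(base_params, "signal_params")) base_params <- do.call(signal_params, base_params)
  structure(list(n_pairs = as.integer(n_pairs), n_triplets = as.integer(n_triplets),
                 singleton_count = as.integer(singleton_count), group_sizes = gs,
                 elements = elements, pathway_effects = pathway_effects,
                 twin_correlation = twin_correlation, base_params = base_params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Net regularity shift for one subject's element: direct element effects plus
# any "Zn-<element>" pair effects for the subject's diagnosis.
regularity_shift <- function(pathway_effects, diagnosis, element) {
  eff <- pathway_effects[[diagnosis]]
  if (is.null(eff)) return(0)
  s <- 0
  if (!is.null(eff[[element]])) s <- s + eff[[element]]
  pair_key <- paste0("Zn-", element)
  if (element != "Zn" && !is.null(eff[[pair_key]])) s <- s + eff[[pair_key]]
  s
}

#' Generate a synthetic twin cohort with per-element tooth profiles
#'
#' Builds the subject table (twin-pair structure, zygosity, covariates,
#' diagnosis) and, for every subject and configured element, a quasi-periodic
#' metal:Ca series.  Members of a pair share a latent exposure factor and a
#' latent regularity deviation, mixed with weight `twin_correlation` for MZ
#' pairs and `twin_correlation / 2` for DZ pairs; gestational age is shared
#' within a pair.  Diagnosis-specific regularity deficits from
#' `pathway_effects` are injected at the generative level, so downstream
#' recovery of group differences is non-circular.
#'
#' @param config A [cohort_config()].
#' @return A list with `subjects` (one row per subject: `subject_id`,
#'   `pair_id`, `zygosity`, `sex`, `gestational_days`, `birth_weight`,
#'   `diagnosis`, `iq`) and `series`, a long data frame with columns
#'   `subject_id`, `element`, `day`, `ratio`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config", call. = FALSE)
  with_seed(config$seed, {
    sizes <- c(rep(2L, config$n_pairs), rep(3L, config$n_triplets),
               rep(1L, config$singleton_count))
    n_groups <- length(sizes)
    n_sub <- sum(sizes)
    pair_id <- rep(sprintf("P%03d", seq_len(n_groups)), times = sizes)
    grp <- rep(seq_len(n_groups), times = sizes)

    zyg_group <- ifelse(sizes == 1L, "SINGLETON",
                        ifelse(stats::runif(n_groups) < 0.5, "MZ", "DZ"))
    zygosity <- zyg_group[grp]

    diagnosis <- sample(rep(names(config$group_sizes), times = config$group_sizes))
    sex <- sample(c("M", "F"), n_sub, replace = TRUE, prob = c(0.6, 0.4))

    # gestation shared within a pair; birth weight subject-level
    gest_group <- pmin(pmax(stats::rnorm(n_groups, 246, 24), 180), 300)
    gestational_days <- round(gest_group[grp])
    birth_weight <- pmax(stats::rnorm(n_sub, 2.4, 0.7), 0.5)
    iq <- round(stats::rnorm(n_sub, 100, 15))

    # latent pair-shared factors: exposure level and regularity deviation
    w <- ifelse(zyg_group == "MZ", config$twin_correlation,
                ifelse(zyg_group == "DZ", config$twin_correlation / 2, 0))
    z_fac_g <- stats::rnorm(n_groups)
    z_reg_g <- stats::rnorm(n_groups)
    wi <- w[grp]
    u_fac <- sqrt(wi) * z_fac_g[grp] + sqrt(1 - wi) * stats::rnorm(n_sub)
    u_reg <- sqrt(wi) * z_reg_g[grp] + sqrt(1 - wi) * stats::rnorm(n_sub)
    subject_factor <- exp(0.25 * u_fac)
    reg_dev <- 0.05 * u_reg

    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_sub)),
      pair_id = pair_id, zygosity = zygosity, sex = sex,
      gestational_days = gestational_days, birth_weight = round(birth_weight, 3),
      diagnosis = diagnosis, iq = iq, stringsAsFactors = FALSE)

    series_seeds <- matrix(sample.int(2147483646L, n_sub * length(config$elements)),
                           nrow = n_sub)
    bp <- config$base_params
    sid <- el_out <- day_out <- val_out <- vector("list", n_sub * length(config$elements))
    k <- 0L
    for (i in seq_len(n_sub)) {
      for (j in seq_along(config$elements)) {
        el <- config$elements[j]
        reg <- bp$regularity + reg_dev[i] +
          regularity_shift(config$pathway_effects, diagnosis[i], el)
        p_i <- bp
        p_i$regularity <- min(max(reg, 0), 1)
        s <- generate_element_series(p_i, subject_factor = subject_factor[i],
                                     rng_seed = series_seeds[i, j],
                                     subject_id = subjects$subject_id[i],
                                     element = el)
        k <- k + 1L
        sid[[k]] <- rep(s$subject_id, length(s$times))
        el_out[[k]] <- rep(s$element, length(s$times))
        day_out[[k]] <- s$times
        val_out[[k]] <- s$values
      }
    }
    series <- data.frame(subject_id = unlist(sid), element = unlist(el_out),
                         day = unlist(day_out), ratio = unlist(val_out),
                         stringsAsFactors = FALSE)
    list(subjects = subjects, series = series)
  })
}

#' Extract one subject/element series from a long series table
#'
#' @param series_df Long data frame with columns `subject_id`, `element`,
#'   `day`, `ratio` (as produced by [generate_cohort()] or
#'   [read_series_csv()]).
#' @param subject_id,element Keys to extract.
#' @return An `element_series`, or `NULL` if absent.
#' @export
get_series <- function(series_df, subject_id, element) {
  sel <- series_df$subject_id == subject_id & series_df$element == element
  if (!any(sel)) return(NULL)
  d <- series_df[sel, , drop = FALSE]
  o <- order(d$day)
  new_element_series(subject_id, element, d$day[o], d$ratio[o])
}
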