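# Shared fixtures: scaled-down cohorts and simulated feature tables keep the
# unit tests fast; study-scale runs live in the acceptance tests.

fast_params <- function(...) {
  signal_params(n_points_mean = 90, day_min = -60, day_max = 90, ...)
}

fast_pathways <- function() {
  pathway_spec(singles = c("Zn", "Cu"), zinc_partners = "Ca")
}

fast_cohort <- function(n_pairs = 4, singleton_count = 0, seed = 42,
                        group_sizes = NULL, effects = list()) {
  total <- 2 * n_pairs + singleton_count
  if (is.null(group_sizes)) {
    n_adhd <- floor(total / 3)
    group_sizes <- c(TD = total - n_adhd, ADHD = n_adhd)
  }
  cohort_config(n_pairs = n_pairs, n_triplets = 0, singleton_count = singleton_count,
                group_sizes = group_sizes, elements = c("Zn", "Cu", "Ca"),
                pathway_effects = effects, base_params = fast_params(), seed = seed)
}

# balanced subject table without any series, for model-level tests
sim_subjects <- function(n_pairs, p_adhd = 0.35, p_asd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_pairs
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  diagnosis <- ifelse(r1 < p_adhd, ifelse(r2 < 0.3, "COMORBID", "ADHD"),
                      ifelse(r2 < p_asd, "ASD", "TD"))
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             pair_id = rep(sprintf("P%04d", seq_len(n_pairs)), each = 2L),
             zygosity = "MZ",
             sex = sample(c("M", "F"), n, TRUE),
             gestational_days = round(stats::rnorm(n, 246, 24)),
             birth_weight = pmax(stats::rnorm(n, 2.4, 0.7), 0.5),
             diagnosis = diagnosis, stringsAsFactors = FALSE)
}

# gaussian feature table with optional class shifts: rows = subjects of the
# given diagnoses, columns named like real pathway features
sim_feature_table <- function(n_per_class = 30, p = 8,
                              class_shift = c(TD = 0, ADHD = 0, ASD = 0, COMORBID = 0),
                              sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- rep(names(class_shift), each = n_per_class)
  n <- length(classes)
  X <- matrix(stats::rnorm(n * p, sd = sd), n, p)
  X <- X + matrix(class_shift[classes], n, p)
  measures <- c("DET", "MDL", "ENTR", "RT")
  cols <- paste0("E", rep(seq_len(ceiling(p / 4)), each = 4), "_", measures)[seq_len(p)]
  colnames(X) <- cols
  tab <- cbind(data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                          stringsAsFactors = FALSE), as.data.frame(X))
  subjects <- data.frame(subject_id = tab$subject_id,
                         pair_id = tab$subject_id, zygosity = "SINGLETON",
                         sex = "M", gestational_days = 246, birth_weight = 2.4,
                         diagnosis = classes, stringsAsFactors = FALSE)
  list(table = tab, subjects = subjects)
}
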