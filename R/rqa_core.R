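#' Embedding and thresholding parameters for recurrence analysis
#'
#' @param m Embedding dimension (>= 1).
#' @param tau Embedding delay in samples (>= 1).
#' @param radius Fixed recurrence threshold; mutually exclusive with
#'   `target_rr`.
#' @param target_rr Target recurrence rate in (0, 1); the threshold is
#'   calibrated per matrix as the empirical quantile of pairwise distances at
#'   this level, making features comparable across subjects whose ratio
#'   signals differ in scale by orders of magnitude.  Exactly one of `radius`
#'   and `target_rr` must be set.
#' @param norm Distance norm in embedding space: `"euclidean"`, `"max"` or
#'   `"manhattan"`.
#' @param theiler Theiler window for auto-recurrence: diagonals with
#'   `|i - j| < theiler` are excluded from line counting (1 = exclude only the
#'   line of identity; cross-recurrence always uses 0).
#' @param l_min Minimum diagonal line length (>= 2) entering determinism,
#'   mean diagonal length and entropy.
#' @param v_min Minimum white vertical line length (reserved for
#'   laminarity-style measures; recurrence time uses all bounded white runs).
#' @param min_embedded Minimum number of embedded points a series must yield
#'   before the feature pipeline reports features (shorter series give
#'   missing values rather than unstable estimates).
#'
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(m = 3L, tau = 1L, radius = NULL, target_rr = 0.10,
                             norm = c("euclidean", "max", "manhattan"),
                             theiler = 1L, l_min = 2L, v_min = 2L,
                             min_embedded = 50L) {
  norm <- match.arg(norm)
  if (!is.numeric(m) || m < 1 || m != round(m)) stop_field("m", "must be an integer >= 1")
  if (!is.numeric(tau) || tau < 1 || tau != round(tau)) stop_field("tau", "must be an integer >= 1")
  if (!is.null(radius)) {
    if (!missing(target_rr) && !is.null(target_rr)) {
      stop_field("radius", "exactly one of radius / target_rr may be set")
    }
    target_rr <- NULL
    if (!is.numeric(radius) || radius <= 0) stop_field("radius", "must be > 0")
  } else {
    if (is.null(target_rr) || !is.numeric(target_rr) || target_rr <= 0 || target_rr >= 1) {
      stop_field("target_rr", "must lie in (0, 1)")
    }
  }
  if (!is.numeric(theiler) || theiler < 0) stop_field("theiler", "must be >= 0")
  if (!is.numeric(l_min) || l_min < 2) stop_field("l_min", "must be >= 2")
  if (!is.numeric(v_min) || v_min < 2) stop_field("v_min", "must be >= 2")
  structure(list(m = as.integer(m), tau = as.integer(tau), radius = radius,
                 target_rr = target_rr, norm = norm, theiler = as.integer(theiler),
                 l_min = as.integer(l_min), v_min = as.integer(v_min),
                 min_embedded = as.integer(min_embedded)),
            class = "embedding_params")
}

#' Time-delay embedding
#'
#' Reconstructs a trajectory in `m`-dimensional delay space: point `i` is
#' `(x[i], x[i + tau], ..., x[i + (m-1) tau])`.
#'
#' @param values Numeric vector, length greater than `(m - 1) * tau`.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return A numeric matrix with `length(values) - (m - 1) * tau` rows and
#'   `m` columns.
#' @export
embed_delay <- function(values, m = 3L, tau = 1L) {
  n <- length(values)
  need <- (m - 1L) * tau + 1L
  if (n < need) {
    stop(sprintf("insufficient length: need at least %d values for m=%d, tau=%d (got %d)",
                 need, m, tau, n), call. = FALSE)
  }
  n_emb <- n - (m - 1L) * tau
  idx <- outer(seq_len(n_emb), (seq_len(m) - 1L) * tau, `+`)
  matrix(values[idx], nrow = n_emb, ncol = m)
}

dist_method <- function(norm) {
  switch(norm, euclidean = "euclidean", max = "maximum", manhattan = "manhattan")
}

# full pairwise distance matrix of one trajectory
auto_distances <- function(traj, norm) {
  as.matrix(stats::dist(traj, method = dist_method(norm)))
}

# rectangular distance matrix between two trajectories (rows of a x rows of b)
cross_distances <- function(a, b, norm) {
  d <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ncol(a))) {
    dk <- abs(outer(a[, k], b[, k], `-`))
    d <- switch(norm,
                euclidean = d + dk^2,
                max = pmax(d, dk),
                manhattan = d + dk)
  }
  if (norm == "euclidean") sqrt(d) else d
}

#' Calibrate a recurrence threshold to a target recurrence rate
#'
#' Returns the empirical quantile, at level `target_rr`, of the pairwise
#' distances between embedded points: all ordered pairs `i != j` for a single
#' trajectory (auto-recurrence), or all cross pairs when a second trajectory
#' is supplied.  Thresholding at the returned radius yields a recurrence rate
#' within one order-statistic step of `target_rr`.
#'
#' @param trajectory Embedded trajectory (matrix) or numeric vector (treated
#'   as 1-d embedding).
#' @param trajectory_b Optional second trajectory for cross-recurrence.
#' @param target_rr Target recurrence rate in (0, 1).
#' @param norm Distance norm (see [embedding_params()]).
#' @return The calibrated radius (a positive number).
#' @export
calibrate_radius <- function(trajectory, trajectory_b = NULL, target_rr = 0.10,
                             norm = "euclidean") {
  if (!is.matrix(trajectory)) trajectory <- matrix(trajectory, ncol = 1L)
  if (target_rr <= 0 || target_rr >= 1) stop_field("target_rr", "must lie in (0, 1)")
  if (is.null(trajectory_b)) {
    d <- stats::dist(trajectory, method = dist_method(norm))
    d <- as.numeric(d)  # each unordered pair once; quantiles match ordered pairs
  } else {
    if (!is.matrix(trajectory_b)) trajectory_b <- matrix(trajectory_b, ncol = 1L)
    d <- as.numeric(cross_distances(trajectory, trajectory_b, norm))
  }
  if (length(d) == 0L) stop("degenerate trajectory: no point pairs", call. = FALSE)
  if (max(d) == 0) stop("degenerate trajectory: all pairwise distances are zero", call. = FALSE)
  k <- ceiling(target_rr * length(d))
  sort(d, partial = k)[k]
}

new_rqa_matrix <- function(R, kind, params, eps) {
  structure(list(R = R, kind = kind, params = params, eps = eps,
                 n = c(nrow(R), ncol(R))),
            class = "rqa_matrix")
}

#' @method print rqa_matrix
#' @export
print.rqa_matrix <- function(x, ...) {
  cat(sprintf("<rqa_matrix> kind=%s %dx%d eps=%.4g RR=%.3f\n",
              x$kind, x$n[1], x$n[2], x$eps, recurrence_rate(x)))
  invisible(x)
}

#' Auto-recurrence matrix of one series
#'
#' Embeds the series (see [embed_delay()]) and thresholds pairwise distances:
#' `R[i, j] = 1` iff `dist(x_i, x_j) <= eps`, with `eps` either fixed
#' (`params$radius`) or calibrated to `params$target_rr` by
#' [calibrate_radius()].  The result is symmetric with a unit main diagonal.
#'
#' @param values Numeric vector (raw series) or an `element_series`.
#' @param params An [embedding_params()].
#' @return An `rqa_matrix` of kind `"AUTO"`.
#' @export
recurrence_matrix <- function(values, params = embedding_params()) {
  if (inherits(values, "element_series")) values <- values$values
  traj <- embed_delay(values, params$m, params$tau)
  d <- auto_distances(traj, params$norm)
  eps <- params$radius %||%
    calibrate_radius(traj, target_rr = params$target_rr, norm = params$norm)
  if (max(d) == 0) stop("degenerate trajectory: all pairwise distances are zero", call. = FALSE)
  new_rqa_matrix(d <= eps, "AUTO", params, eps)
}

#' Cross-recurrence matrix of two series
#'
#' The two series are restricted to their overlapping day interval, linearly
#' interpolated onto a common uniform grid whose length is the smaller of the
#' two point counts within the overlap, z-normalised independently (so affine
#' differences in scale and offset drop out), embedded with the shared
#' `(m, tau)`, and thresholded: `R[i, j] = 1` iff
#' `dist(a_i, b_j) <= eps`, with `eps` calibrated on the pooled cross
#' distances (or fixed via `params$radius`).  Cross matrices are not
#' symmetric in general and carry no enforced main diagonal; no Theiler
#' window is applied.
#'
#' @param series_a,series_b `element_series` objects (or lists with `times`
#'   and `values`).
#' @param params An [embedding_params()].
#' @return An `rqa_matrix` of kind `"CROSS"`.
#' @export
cross_recurrence_matrix <- function(series_a, series_b, params = embedding_params()) {
  lo <- max(min(series_a$times), min(series_b$times))
  hi <- min(max(series_a$times), max(series_b$times))
  if (hi <= lo) stop("disjoint supports: the two series do not overlap in time", call. = FALSE)
  n_a <- sum(series_a$times >= lo & series_a$times <= hi)
  n_b <- sum(series_b$times >= lo & series_b$times <= hi)
  L <- min(n_a, n_b)
  need <- (params$m - 1L) * params$tau + 2L
  if (L < need) {
    stop(sprintf("insufficient length: overlap supports only %d points, need %d", L, need),
         call. = FALSE)
  }
  grid <- seq(lo, hi, length.out = L)
  va <- stats::approx(series_a$times, series_a$values, xout = grid)$y
  vb <- stats::approx(series_b$times, series_b$values, xout = grid)$y
  zn <- function(v, which) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("degenerate trajectory: series %s has zero variance over the overlap", which),
           call. = FALSE)
    }
    (v - mean(v)) / s
  }
  ta <- embed_delay(zn(va, "A"), params$m, params$tau)
  tb <- embed_delay(zn(vb, "B"), params$m, params$tau)
  d <- cross_distances(ta, tb, params$norm)
  eps <- params$radius %||%
    calibrate_radius(ta, tb, target_rr = params$target_rr, norm = params$norm)
  new_rqa_matrix(d <= eps, "CROSS", params, eps)
}

#' Recurrence rate over the unmasked region
#'
#' @param x An `rqa_matrix`.
#' @return Fraction of unmasked cells that are recurrent.
#' @export
recurrence_rate <- function(x) {
  R <- x$R
  n <- nrow(R)
  if (x$kind != "AUTO" || x$params$theiler <= 0) return(sum(R) / length(R))
  w <- x$params$theiler
  band_cells <- 0L
  band_ones <- 0L
  for (k in seq.int(-w + 1L, w - 1L)) {
    i <- seq.int(max(1L, 1L - k), min(n, n - k))
    band_cells <- band_cells + length(i)
    band_ones <- band_ones + sum(R[cbind(i, i + k)])
  }
  (sum(R) - band_ones) / (length(R) - band_cells)
}

#' Diagonal and white-vertical line histograms of a recurrence matrix
#'
#' Counts maximal diagonal runs of recurrent cells (cyclical events) and
#' maximal white vertical runs between recurrences within columns (the gaps
#' that define recurrence time).  For auto-recurrence matrices, diagonals
#' within the Theiler window are excluded entirely (default window 1 masks
#' only the line of identity); cross matrices are counted in full.
#'
#' @param x An `rqa_matrix`, or a plain logical/binary matrix (then treated
#'   with `theiler` and `kind` as given).
#' @param theiler,kind Used only when `x` is a plain matrix.
#' @return A `line_histogram`: list with integer vectors `diagonal` and
#'   `white`, where element `l` counts maximal runs of length `l`.
#' @export
diagonal_histogram <- function(x, theiler = 1L, kind = "AUTO") {
  if (inherits(x, "rqa_matrix")) {
    R <- x$R
    theiler <- x$params$theiler
    kind <- x$kind
  } else {
    R <- x != 0
    storage.mode(R) <- "logical"
  }
  h <- line_histograms(R, as.integer(theiler), identical(kind, "AUTO"))
  structure(list(diagonal = h$diagonal, white = h$white), class = "line_histogram")
}

entropy_from_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Dynamical features of a recurrence matrix
#'
#' Computes the recurrence rate and the four line-based measures of cyclical
#' structure:
#' \describe{
#'   \item{DET}{determinism, the fraction of recurrence points on diagonal
#'     lines of length at least `l_min` — cycle regularity;}
#'   \item{MDL}{mean diagonal line length — cycle duration;}
#'   \item{ENTR}{Shannon entropy (natural log) of the qualifying diagonal
#'     line-length distribution — cycle-duration complexity;}
#'   \item{RT}{type-2 recurrence time, the mean white vertical line length —
#'     the interval between cycles.}
#' }
#' Features whose supporting histogram is empty are returned as `NA`
#' (explicit missing, never 0): MDL/ENTR when no diagonal reaches `l_min`,
#' DET when the matrix has no recurrence points outside the Theiler window,
#' RT when no white gap is bounded by recurrences.
#'
#' @param x An `rqa_matrix`, or a `line_histogram` (then `rr` should be
#'   supplied if a recurrence rate is wanted).
#' @param l_min Minimum diagonal line length; defaults to the matrix's
#'   embedding parameters.
#' @param rr Recurrence rate to report when `x` is a bare histogram.
#' @return An `rqa_features` object: named list `RR`, `DET`, `MDL`, `ENTR`,
#'   `RT`.
#' @export
rqa_features <- function(x, l_min = NULL, rr = NA_real_) {
  if (inherits(x, "rqa_matrix")) {
    h <- diagonal_histogram(x)
    l_min <- l_min %||% x$params$l_min
    rr <- recurrence_rate(x)
  } else if (inherits(x, "line_histogram")) {
    h <- x
    l_min <- l_min %||% 2L
  } else {
    stop("x must be an rqa_matrix or line_histogram", call. = FALSE)
  }
  P <- h$diagonal
  lens <- seq_along(P)
  total_pts <- sum(lens * P)
  long <- lens >= l_min
  n_long <- sum(P[long])
  det <- if (total_pts > 0) sum(lens[long] * P[long]) / total_pts else NA_real_
  mdl <- if (n_long > 0) sum(lens[long] * P[long]) / n_long else NA_real_
  entr <- if (n_long > 0) entropy_from_counts(P[long][P[long] > 0]) else NA_real_
  W <- h$white
  n_white <- sum(W)
  rt <- if (n_white > 0) sum(seq_along(W) * W) / n_white else NA_real_
  structure(list(RR = rr, DET = det, MDL = mdl, ENTR = entr, RT = rt),
            class = "rqa_features")
}

#' @method print rqa_features
#' @export
print.rqa_features <- function(x, ...) {
  cat(sprintf("<rqa_features> RR=%.3f DET=%.3f MDL=%.2f ENTR=%.3f RT=%.2f\n",
              x$RR, x$DET, x$MDL, x$ENTR, x$RT))
  invisible(x)
}

#' One-call RQA of a single series
#'
#' @param values Numeric vector or `element_series`.
#' @param params An [embedding_params()].
#' @return An `rqa_features` object.
#' @export
rqa <- function(values, params = embedding_params()) {
  rqa_features(recurrence_matrix(values, params))
}

#' One-call cross-RQA of two series
#'
#' @param series_a,series_b `element_series` objects.
#' @param params An [embedding_params()].
#' @return An `rqa_features` object.
#' @export
crqa <- function(series_a, series_b, params = embedding_params()) {
  rqa_features(cross_recurrence_matrix(series_a, series_b, params))
}
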