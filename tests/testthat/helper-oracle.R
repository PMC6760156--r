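# Brute-force recurrence-quantification oracle, independent of the package's
# compiled run-length path: walks every diagonal and every column cell by
# cell in plain R.  Used to validate diagonal_histogram()/rqa_features().

oracle_line_hist <- function(R, theiler = 1L, is_auto = TRUE) {
  n <- nrow(R)
  m <- ncol(R)
  dcounts <- integer(max(n, m))
  for (k in seq.int(-(n - 1L), m - 1L)) {
    if (is_auto && abs(k) < theiler) next
    i <- if (k < 0) -k + 1L else 1L
    j <- if (k < 0) 1L else k + 1L
    run <- 0L
    while (i <= n && j <= m) {
      if (R[i, j]) {
        run <- run + 1L
      } else if (run > 0L) {
        dcounts[run] <- dcounts[run] + 1L
        run <- 0L
      }
      i <- i + 1L
      j <- j + 1L
    }
    if (run > 0L) dcounts[run] <- dcounts[run] + 1L
  }
  wcounts <- integer(max(n, m))
  for (j in seq_len(m)) {
    rec <- R[, j]
    if (is_auto && theiler > 0L) {
      rec <- rec | abs(seq_len(n) - j) < theiler
    }
    at <- which(rec)
    if (length(at) >= 2L) {
      gaps <- diff(at) - 1L
      for (g in gaps[gaps > 0L]) wcounts[g] <- wcounts[g] + 1L
    }
  }
  list(diagonal = dcounts, white = wcounts)
}

oracle_features <- function(R, theiler = 1L, is_auto = TRUE, l_min = 2L) {
  h <- oracle_line_hist(R, theiler, is_auto)
  P <- h$diagonal
  ls <- seq_along(P)
  tot <- sum(ls * P)
  qual <- ls >= l_min
  det <- if (tot > 0) sum(ls[qual] * P[qual]) / tot else NA_real_
  nq <- sum(P[qual])
  mdl <- if (nq > 0) sum(ls[qual] * P[qual]) / nq else NA_real_
  entr <- if (nq > 0) {
    pr <- P[qual][P[qual] > 0] / nq
    -sum(pr * log(pr))
  } else NA_real_
  W <- h$white
  rt <- if (sum(W) > 0) sum(seq_along(W) * W) / sum(W) else NA_real_
  list(DET = det, MDL = mdl, ENTR = entr, RT = rt)
}

# strip trailing zeros so histograms of different allocated lengths compare
trim_counts <- function(x) {
  last <- max(c(0L, which(x > 0L)))
  x[seq_len(last)]
}

random_binary_matrix <- function(n, density) {
  R <- matrix(stats::runif(n * n) < density, n, n)
  R <- R | t(R)
  diag(R) <- TRUE
  R
}
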