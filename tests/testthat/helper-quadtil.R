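# Shared fixtures and independent oracles for the test suite.

# Construct a subject_pattern directly (mm coordinates), bypassing file
# IO, with an explicit window when the bounding box is not wanted.
make_pattern <- function(cancer, cd8, window = NULL, dist_um = NULL,
                         subject_id = "T1") {
  cancer <- as.data.frame(cancer); names(cancer) <- c("x", "y")
  cd8 <- as.data.frame(cd8)
  if (ncol(cd8) == 2) names(cd8) <- c("x", "y") else
    names(cd8) <- c("x", "y", "dist_um")
  if (!"dist_um" %in% names(cd8))
    cd8$dist_um <- if (is.null(dist_um)) rep(NA_real_, nrow(cd8)) else
      dist_um
  if (is.null(window)) {
    allx <- c(cancer$x, cd8$x); ally <- c(cancer$y, cd8$y)
    window <- c(min(allx), max(allx), min(ally), max(ally))
  }
  structure(list(subject_id = subject_id, cancer = cancer, cd8 = cd8,
                 window = window, dist_source = NA_character_),
            class = "subject_pattern")
}

# O(n^2) exhaustive nearest-neighbour oracle, mm in / um out.
brute_nearest_um <- function(pts, ref) {
  pts <- as.matrix(pts); ref <- as.matrix(ref)
  vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt((pts[i, 1] - ref[, 1])^2 + (pts[i, 2] - ref[, 2])^2))
  }, numeric(1)) * 1000
}

# Point-by-point quadrat binning oracle mirroring the stated half-open
# convention (last row/column closed).
brute_bin <- function(x, y, window, s) {
  n_cols <- ceiling((window[2] - window[1]) / s)
  n_rows <- ceiling((window[4] - window[3]) / s)
  m <- matrix(0L, n_rows, n_cols)
  for (k in seq_along(x)) {
    j <- min(floor((x[k] - window[1]) / s), n_cols - 1) + 1
    i <- min(floor((y[k] - window[3]) / s), n_rows - 1) + 1
    m[i, j] <- m[i, j] + 1L
  }
  m
}

# Efron-approximation Cox partial log-likelihood (negated), written from
# the definition for use as a brute-force optimization oracle.
efron_neg_loglik <- function(beta, time, status, X) {
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(sum(w[R]) - ((seq_len(d) - 1) / d) * sumD))
  }
  -ll
}

# Small fast clinical cohort: covariates + survival only, true slopes
# drawn around the arm medians.
quick_clinical_cohort <- function(n_naive, n_nat,
                                  params = synthetic_defaults(),
                                  sdlog = params$beta_sdlog) {
  treat <- rep(c("naive", "NAT"), c(n_naive, n_nat))
  n <- length(treat)
  ids <- sprintf("P%03d", seq_len(n))
  med <- ifelse(treat == "NAT", params$beta_median_nat,
                params$beta_median_naive)
  beta <- stats::rlnorm(n, log(med), sdlog)
  clin <- simulate_clinical_and_survival(ids, treat, beta, params)
  cbind(clin, beta = beta)
}
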