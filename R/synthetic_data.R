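# Synthetic-cohort generator with known ground truth. Emulates the
# data-generating structure the analysis models assume: Thomas-cluster
# cancer patterns (gland-like clumps), CD8 counts that follow the
# quadrat-level NB law exp(alpha + beta * cancer), clinical covariates
# with cohort-like margins, and proportional-hazards survival with
# uniform censoring.

#' Default synthetic-cohort parameters
#'
#' The defaults are calibrated to the cohort the models were built for:
#' 27 naive + 39 NAT subjects, arm slope medians 0.0078 (naive) and
#' 0.017 (NAT), NB size theta = 2, an 8 x 6 mm window tessellated into
#' 0.5 mm quadrats (192 of them), roughly 28 cancer and 5 CD8 cells per
#' active quadrat, a protective HigherSlope hazard ratio of 0.33, and a
#' censoring scale giving roughly 73% observed events.
#'
#' @return named list of generator parameters.
#' @export
synthetic_defaults <- function() {
  list(
    n_naive = 27L, n_nat = 39L,
    window = c(0, 8, 0, 6),           # mm
    quadrat_mm = 0.5,
    # Thomas process for cancer cells: kappa parents/mm^2, mu offspring
    # per parent, sigma mm displacement; kappa*mu = 114 cells/mm^2 in
    # both arms, but the NAT arm has many small glands (more homogeneous,
    # quadrat-wise SD lower by roughly 12 counts) and the naive arm few
    # large ones, reproducing the heterogeneity contrast.
    kappa = c(naive = 3, NAT = 12), mu = c(naive = 38, NAT = 9.5),
    sigma = 0.1,
    # CD8 | cancer quadrat law
    beta_median_naive = 0.0078, beta_median_nat = 0.017,
    beta_sdlog = 0.6,
    alpha0 = log(2.4), alpha_sd = 0.5,
    theta = 2,
    # a background of CD8 cells beyond the TIL band, removed by the
    # 50-um filter (fraction of the TIL count)
    background_frac = 0.3,
    # survival
    hr_slope_group = 0.33, hr_nat = 2.0,
    log_hr_grade = c(G2 = 0.5, G3 = 0.8),
    log_hr_stage = c(II = 0.5, III = 0.9, IV = 1.2),
    log_hr_age_upper = 0.2,
    baseline_median_days = 678,
    lp_center = 0.92,                 # expected linear predictor at the
                                      # cohort covariate mix
    censor_max_days = 3500,
    expected_median_ci = c(439, 1125),
    # covariate margins
    p_male = 0.545,
    grade_probs = c(G1 = 0.182, G2 = 0.5, G3 = 0.318),
    stage_probs = c(I = 0.242, II = 0.576, III = 0.152, IV = 0.03),
    age_range = c(46, 88), age_median = 70
  )
}

# One reproducible sub-seed per subject (and one for the clinical layer)
# derived from the master seed, so cohorts are stable under
# subject-level parallelism.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a gland-like cancer-cell pattern (Thomas cluster process)
#'
#' Poisson(kappa * area) parent "glands" with Poisson(mu) offspring cells
#' displaced by an isotropic Gaussian(sigma). Parents are drawn on a
#' window dilated by 4 sigma so the process restricted to the window is
#' stationary; offspring outside the window are discarded, making the
#' expected count kappa * area * mu (up to the negligible > 4 sigma
#' tail).
#'
#' @param window `c(xmin, xmax, ymin, ymax)`, mm.
#' @param kappa parent intensity per mm^2.
#' @param mu mean offspring per parent.
#' @param sigma offspring displacement SD, mm.
#' @return two-column matrix of points, mm.
#' @export
simulate_cancer_pattern <- function(window, kappa = 6, mu = 19,
                                    sigma = 0.1) {
  stopifnot(kappa > 0, mu > 0, sigma >= 0)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  if (kappa * area * mu > 1e6)
    stop("expected point count exceeds 1e6; refusing desk-scale guard")
  pad <- 4 * sigma
  ew <- window + c(-pad, pad, -pad, pad)
  earea <- (ew[2] - ew[1]) * (ew[4] - ew[3])
  n_parents <- stats::rpois(1, kappa * earea)
  if (n_parents == 0L) return(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y"))))
  px <- stats::runif(n_parents, ew[1], ew[2])
  py <- stats::runif(n_parents, ew[3], ew[4])
  n_off <- stats::rpois(n_parents, mu)
  x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  keep <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
  cbind(x = x[keep], y = y[keep])
}

#' Simulate CD8 cells conditional on a cancer pattern
#'
#' Two generative modes. `"quadrat"` is the exact twin of the fitted
#' model: for each quadrat of `grid` a CD8 count is drawn from
#' NB(mean = exp(alpha + beta * cancer_count), theta) and that many
#' points are placed uniformly inside the quadrat (clipped to the
#' window). `"continuous"` draws an inhomogeneous Poisson pattern with
#' intensity exp(a + b * smoothed cancer density), discretised at the
#' density-map resolution; with `b = 0` it reduces to a homogeneous
#' Poisson process.
#'
#' @param grid `quadrat_grid` built from the cancer pattern.
#' @param alpha,beta,theta quadrat-law parameters (`"quadrat"` mode).
#' @param mode `"quadrat"` or `"continuous"`.
#' @param a,b log-intensity parameters (`"continuous"` mode; intensity
#'   per mm^2).
#' @param bandwidth,resolution density-map controls (`"continuous"`).
#' @param window observation window, mm.
#' @param cancer_points cancer pattern (`"continuous"` mode).
#' @return two-column matrix of CD8 points, mm.
#' @export
simulate_cd8_given_cancer <- function(grid = NULL, alpha, beta, theta = 2,
                                      mode = c("quadrat", "continuous"),
                                      a = NULL, b = NULL,
                                      cancer_points = NULL, window = NULL,
                                      bandwidth = 0.25, resolution = 0.1) {
  mode <- match.arg(mode)
  if (mode == "quadrat") {
    stopifnot(inherits(grid, "quadrat_grid"))
    s <- grid$cell_size; o <- grid$origin
    win <- c(o[1], o[1] + grid$n_cols * s, o[2], o[2] + grid$n_rows * s)
    mu_q <- exp(alpha + beta * grid$cancer_counts)
    counts <- matrix(stats::rnbinom(length(mu_q), mu = mu_q, size = theta),
                     grid$n_rows, grid$n_cols)
    pts <- lapply(which(counts > 0), function(lin) {
      i <- (lin - 1L) %% grid$n_rows + 1L
      j <- (lin - 1L) %/% grid$n_rows + 1L
      n <- counts[i, j]
      cbind(x = stats::runif(n, o[1] + (j - 1) * s, o[1] + j * s),
            y = stats::runif(n, o[2] + (i - 1) * s, o[2] + i * s))
    })
    out <- if (length(pts)) do.call(rbind, pts) else
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    # partial edge quadrats can overhang the observation window; clip so
    # every emitted point lies inside it
    clip <- if (is.null(window)) win else window
    if (nrow(out)) {
      out[, 1] <- pmin(pmax(out[, 1], clip[1]), clip[2])
      out[, 2] <- pmin(pmax(out[, 2], clip[3]), clip[4])
    }
    return(out)
  }
  # continuous mode
  stopifnot(!is.null(cancer_points), !is.null(window),
            !is.null(a), !is.null(b))
  if (b == 0) {
    lam <- exp(a)
    area <- (window[2] - window[1]) * (window[4] - window[3])
    n <- stats::rpois(1, lam * area)
    return(cbind(x = stats::runif(n, window[1], window[2]),
                 y = stats::runif(n, window[3], window[4])))
  }
  dm <- density_map(cancer_points, window, bandwidth = bandwidth,
                    resolution = resolution)
  lam <- exp(a + b * dm$values)           # per mm^2 at pixel centres
  counts <- stats::rpois(length(lam), lam * resolution^2)
  idx <- which(counts > 0)
  pts <- lapply(idx, function(lin) {
    i <- (lin - 1L) %% nrow(lam) + 1L
    j <- (lin - 1L) %/% nrow(lam) + 1L
    n <- counts[lin]
    cbind(x = stats::runif(n, dm$x[j] - resolution / 2,
                           dm$x[j] + resolution / 2),
          y = stats::runif(n, dm$y[i] - resolution / 2,
                           dm$y[i] + resolution / 2))
  })
  if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
}

#' Fast quadrat-count simulator (no point placement)
#'
#' Draws paired (cancer, cd8) quadrat counts directly from the marginal /
#' conditional NB laws. This is the workhorse of the parameter-recovery
#' checks: cancer counts are NB(cancer_mean, cancer_theta), CD8 counts
#' are NB(exp(alpha + beta * cancer), theta).
#'
#' By default the quadrats emulate the annotated tumor region, where
#' every quadrat contains at least one cancer cell: the cancer marginal
#' is zero-truncated and zero-zero pairs cannot arise. With
#' `tumor_quadrats_only = FALSE` cancer-free quadrats are generated too
#' and zero-zero pairs are dropped, as the grid stage would drop them;
#' note that this selection keeps only the cd8-positive among the
#' cancer-free quadrats and therefore attenuates a fitted slope slightly
#' (see the methods vignette).
#'
#' @param n_quadrats number of quadrats to draw.
#' @param alpha,beta,theta CD8 law.
#' @param cancer_mean,cancer_theta cancer-count marginal (defaults give a
#'   quadrat-wise mean near 28 and SD near 26).
#' @param tumor_quadrats_only zero-truncate the cancer marginal
#'   (default TRUE).
#' @return `data.frame(cancer, cd8)` of active quadrats.
#' @export
simulate_quadrat_counts <- function(n_quadrats, alpha, beta, theta = 2,
                                    cancer_mean = 28, cancer_theta = 1.2,
                                    tumor_quadrats_only = TRUE) {
  cancer <- stats::rnbinom(n_quadrats, mu = cancer_mean,
                           size = cancer_theta)
  if (tumor_quadrats_only) {
    while (any(cancer == 0L))          # resample the zero draws
      cancer[cancer == 0L] <- stats::rnbinom(sum(cancer == 0L),
                                             mu = cancer_mean,
                                             size = cancer_theta)
  }
  cd8 <- stats::rnbinom(n_quadrats, mu = exp(alpha + beta * cancer),
                        size = theta)
  df <- data.frame(cancer = cancer, cd8 = cd8)
  df[df$cancer + df$cd8 > 0, , drop = FALSE]
}

#' Simulate clinical covariates and survival for a cohort
#'
#' Covariates follow cohort-like margins (roughly 55% male, median age
#' 70, grade mix 18/50/32%, stage mix 24/58/15/3%). Survival is
#' exponential with hazard `log(2)/baseline_median * exp(lp - lp_center)`
#' where the linear predictor carries the slope-group log-HR (default
#' log 0.33, slope at or above the true cohort median), the treatment,
#' grade, stage and age-category log-HRs; censoring is independent
#' Uniform(0, censor_max_days), chosen so about 73% of subjects have an
#' observed event.
#'
#' @param subject_id character vector.
#' @param treatment factor/character, `naive`/`NAT`.
#' @param beta per-subject true (or fitted) slopes; the median split uses
#'   these.
#' @param params parameter list, see [synthetic_defaults()].
#' @return clinical `data.frame` (validated, factor-coded).
#' @export
simulate_clinical_and_survival <- function(subject_id, treatment, beta,
                                           params = synthetic_defaults()) {
  n <- length(subject_id)
  stopifnot(length(treatment) == n, length(beta) == n)
  p <- params
  sex <- sample(c("M", "F"), n, replace = TRUE,
                prob = c(p$p_male, 1 - p$p_male))
  # uniform/normal mixture spanning the cohort age range; the normal
  # component is placed so the mixture median sits at the 70-year cutoff
  age <- round(stats::runif(n, p$age_range[1], p$age_range[2]) * 0.5 +
               stats::rnorm(n, p$age_median + 3, 6) * 0.5)
  age <- pmin(pmax(age, p$age_range[1]), p$age_range[2])
  grade <- sample(names(p$grade_probs), n, TRUE, p$grade_probs)
  stage <- sample(names(p$stage_probs), n, TRUE, p$stage_probs)
  higher <- beta >= stats::median(beta)
  lp <- log(p$hr_slope_group) * higher +
    log(p$hr_nat) * (treatment == "NAT") +
    ifelse(grade == "G1", 0, p$log_hr_grade[grade]) +
    ifelse(stage == "I", 0, p$log_hr_stage[stage]) +
    p$log_hr_age_upper * (age >= p$age_median)
  rate <- log(2) / p$baseline_median_days * exp(lp - p$lp_center)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, p$censor_max_days)
  out <- data.frame(
    subject_id = subject_id,
    treatment = as.character(treatment), sex = sex, age = age,
    grade = grade, stage = stage,
    time = pmax(pmin(t_event, t_cens), 1),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE)
  validate_clinical(as_clinical_factors(out))
}

#' Simulate a full synthetic cohort with known truth
#'
#' Generates, per subject: a Thomas-cluster cancer pattern; a true slope
#' beta drawn lognormally around the arm median; CD8 TILs from the
#' quadrat-level NB law (these carry a platform-style `dist_um` in
#' [0, 50], marking them as within the TIL band of a gland); and an
#' optional background of CD8 cells beyond 50 um that the TIL filter
#' must remove. Clinical covariates and survival come from
#' [simulate_clinical_and_survival()]. Everything is driven by
#' per-subject RNG streams derived from `seed`, so the same seed
#' reproduces the same cohort exactly.
#'
#' @param seed master seed.
#' @param params parameter list, see [synthetic_defaults()]; pass a
#'   modified copy to change conditions.
#' @param n_inadequate number of subjects seeded to violate the
#'   minimum-count inclusion rule (their cell numbers are truncated
#'   below 10; the last such subject is CD8-deficient, the others
#'   cancer-deficient).
#' @return list `patterns` (list of `subject_pattern`), `clinical`
#'   (`data.frame`), `truth` (list: per-subject alpha/beta/theta, arm
#'   medians, process and survival parameters, seed).
#' @export
simulate_cohort <- function(seed = 1, params = synthetic_defaults(),
                            n_inadequate = 0L) {
  p <- params
  n <- p$n_naive + p$n_nat
  treatment <- rep(c("naive", "NAT"), c(p$n_naive, p$n_nat))
  ids <- sprintf("S%03d", seq_len(n))
  seeds <- derive_seeds(seed, n + 1L)

  alpha <- beta <- numeric(n)
  patterns <- vector("list", n)
  inadequate <- if (n_inadequate > 0L)
    utils::tail(seq_len(n), n_inadequate) else integer(0)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    med <- if (treatment[i] == "NAT") p$beta_median_nat else
      p$beta_median_naive
    beta[i] <- stats::rlnorm(1, log(med), p$beta_sdlog)
    alpha[i] <- stats::rnorm(1, p$alpha0, p$alpha_sd)
    arm_par <- function(v) if (length(v) > 1L) v[[treatment[i]]] else v
    cancer <- simulate_cancer_pattern(p$window, arm_par(p$kappa),
                                      arm_par(p$mu), p$sigma)
    pat <- structure(list(
      subject_id = ids[i],
      cancer = data.frame(x = cancer[, 1], y = cancer[, 2]),
      cd8 = data.frame(x = numeric(0), y = numeric(0),
                       dist_um = numeric(0)),
      window = p$window, dist_source = NA_character_),
      class = "subject_pattern")
    grid <- make_quadrat_grid(pat, p$quadrat_mm)
    til <- simulate_cd8_given_cancer(grid, alpha[i], beta[i], p$theta)
    n_til <- nrow(til)
    n_bg <- stats::rpois(1, p$background_frac * max(n_til, 1))
    bg <- cbind(x = stats::runif(n_bg, p$window[1], p$window[2]),
                y = stats::runif(n_bg, p$window[3], p$window[4]))
    pat$cd8 <- data.frame(
      x = c(til[, 1], bg[, 1]), y = c(til[, 2], bg[, 2]),
      dist_um = c(stats::runif(n_til, 0, 50),
                  stats::runif(n_bg, 50.01, 1000)))
    if (i %in% inadequate) {
      if (i == max(inadequate)) {          # CD8-deficient subject
        pat$cd8 <- pat$cd8[seq_len(min(9L, nrow(pat$cd8))), , drop = FALSE]
      } else {                             # cancer-deficient subject
        pat$cancer <- pat$cancer[seq_len(min(9L, nrow(pat$cancer))), ,
                                 drop = FALSE]
      }
    }
    patterns[[i]] <- pat
  }
  set.seed(seeds[n + 1L])
  clinical <- simulate_clinical_and_survival(ids, treatment, beta, p)
  truth <- list(seed = seed, subject_id = ids, treatment = treatment,
                alpha = alpha, beta = beta, theta = p$theta,
                arm_medians = c(naive = p$beta_median_naive,
                                NAT = p$beta_median_nat),
                params = p, inadequate = ids[inadequate])
  list(patterns = patterns, clinical = clinical, truth = truth)
}
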