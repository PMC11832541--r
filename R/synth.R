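#' Ground-truth state sequence for synthetic timeseries
#'
#' A sequence of latent connectivity states, one per generation block.
#' `REDUNDANT` blocks are drawn from a covariance whose strongest couplings
#' form a network that is two-connected at its own connection density;
#' `FRAGILE` blocks from a spanning-path (tree-like) covariance that is
#' one-connected well before it is two-connected.
#'
#' @param labels Character vector of `"REDUNDANT"` / `"FRAGILE"` tags.
#' @return Object of class `state_sequence`.
#' @export
state_sequence <- function(labels) {
  labels <- toupper(as.character(labels))
  if (length(labels) < 1L || !all(labels %in% c("REDUNDANT", "FRAGILE"))) {
    stop("state labels must be 'REDUNDANT' or 'FRAGILE'")
  }
  structure(list(labels = labels, n_blocks = length(labels)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence:", paste(x$labels, collapse = " -> "), "\n")
  invisible(x)
}

# Signal for one REDUNDANT block. Two communities share one signal each
# (intra-community correlations sit at the snr ceiling and are tightly
# clustered), community signals are coupled through a global component
# (uniform weaker inter-community band), and three designated vertex-disjoint
# cross-community pairs get a small extra shared component, so the population
# correlation matrix thresholds to a two-connected network at the same grid
# density at which it first becomes connected.
redundant_block_signal <- function(n_regions, n_vol, rho = 0.35,
                                   bridge_boost = 0.45) {
  comm <- sort(rep(1:2, length.out = n_regions))
  G <- stats::rnorm(n_vol)
  g1 <- sqrt(rho) * G + sqrt(1 - rho) * stats::rnorm(n_vol)
  g2 <- sqrt(rho) * G + sqrt(1 - rho) * stats::rnorm(n_vol)
  X <- matrix(0, n_vol, n_regions)
  X[, comm == 1L] <- g1
  X[, comm == 2L] <- g2
  # designated bridges: first regions of community 1 paired with first
  # regions of community 2, disjoint by construction
  n1 <- sum(comm == 1L)
  n_bridge <- min(4L, n1, n_regions - n1)
  for (b in seq_len(n_bridge)) {
    shared <- bridge_boost * stats::rnorm(n_vol)
    X[, b] <- X[, b] + shared
    X[, n1 + b] <- X[, n1 + b] + shared
  }
  scale(X, center = FALSE, scale = apply(X, 2, stats::sd))
}

# Signal for one FRAGILE block: an AR(1) chain across a fixed random region
# order — a spanning path whose correlations decay geometrically with chain
# distance, so the thresholded network connects as a tree.
fragile_block_signal <- function(n_regions, n_vol, order_perm, phi = 0.7) {
  Z <- matrix(stats::rnorm(n_vol * n_regions), n_vol, n_regions)
  X <- matrix(0, n_vol, n_regions)
  X[, order_perm[1L]] <- Z[, 1L]
  for (i in seq_len(n_regions)[-1L]) {
    X[, order_perm[i]] <- phi * X[, order_perm[i - 1L]] +
      sqrt(1 - phi^2) * Z[, i]
  }
  X
}

#' Generate a synthetic regional timeseries with known state structure
#'
#' Produces a volumes x regions timeseries whose covariance alternates
#' between a redundant (two-connected at its connection density) and a
#' fragile (tree-like) state according to `state_seq`. Blocks are of equal
#' length (`n_volumes` must be divisible by the number of blocks) so that
#' block boundaries can be aligned with analysis windows and ground-truth
#' labels stay unambiguous. Independent measurement noise with variance
#' `1/snr` relative to unit signal variance is added throughout.
#'
#' @param n_regions Number of regions (>= 4).
#' @param n_volumes Number of volumes; must be a multiple of the number of
#'   blocks in `state_seq`.
#' @param state_seq A [state_sequence()] (or character vector coerced to one).
#' @param snr Positive signal-to-noise variance ratio.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param tr_seconds Repetition time metadata (default 3).
#' @param subject_id,session_id Identifier metadata.
#' @return A [regional_ts()] with a `truth` attribute recording the state
#'   sequence, block length and generator parameters.
#' @export
gen_timeseries <- function(n_regions, n_volumes, state_seq, snr, seed,
                           tr_seconds = 3, subject_id = "synthetic",
                           session_id = "1") {
  stop_if_not_scalar_count(n_regions, "n_regions", min = 4L)
  stop_if_not_scalar_count(n_volumes, "n_volumes", min = 2L)
  if (!inherits(state_seq, "state_sequence")) {
    state_seq <- state_sequence(state_seq)
  }
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0) {
    stop("'snr' must be a single positive number")
  }
  n_blocks <- state_seq$n_blocks
  if (n_volumes %% n_blocks != 0L) {
    stop("'n_volumes' must be divisible by the number of state blocks")
  }
  block_len <- n_volumes %/% n_blocks

  set.seed(derive_seed(seed, 0L))
  chain_order <- sample.int(n_regions)  # fixed fragile chain for this call

  X <- matrix(0, n_volumes, n_regions)
  for (b in seq_len(n_blocks)) {
    set.seed(derive_seed(seed, b))
    rows <- ((b - 1L) * block_len + 1L):(b * block_len)
    X[rows, ] <- if (state_seq$labels[b] == "REDUNDANT") {
      redundant_block_signal(n_regions, block_len)
    } else {
      fragile_block_signal(n_regions, block_len, chain_order)
    }
  }
  set.seed(derive_seed(seed, n_blocks + 1L))
  X <- X + matrix(stats::rnorm(n_volumes * n_regions, sd = sqrt(1 / snr)),
                  n_volumes, n_regions)
  ts <- regional_ts(X, tr_seconds = tr_seconds, subject_id = subject_id,
                    session_id = session_id)
  attr(ts, "truth") <- list(state_labels = state_seq$labels,
                            block_length = block_len, snr = snr, seed = seed)
  ts
}

#' Default loading pattern of the 13-test cognitive battery
#'
#' Loadings of three latent domain factors (episodic, semantic, executive)
#' on the 13 cognitive tests: six episodic recall tests, three
#' vocabulary/reading tests, four executive tests. The numeric values are
#' calibrated so that, together with [default_method_loadings()] and the
#' default test-specific noise, the population eigen-spectrum of the
#' simulated battery reproduces the gradually decaying scree typical of
#' such batteries (dominant episodic axis ~42% of variance, semantic ~16%,
#' a weak executive component ~9%, then a slowly decaying tail), which
#' makes the chord-distance elbow sit at 3. The executive tests carry a
#' small cross-loading on the episodic/general axis, as executive tasks do
#' in practice.
#'
#' @return A 13 x 3 numeric matrix with test names as row names.
#' @export
default_cognitive_loadings <- function() {
  tests <- cognitive_battery()
  L <- matrix(0, 13L, 3L,
              dimnames = list(tests, c("episodic", "semantic", "executive")))
  L[1:6, "episodic"] <- sqrt(0.80)
  L[1:3, "episodic"] <- sqrt(0.69)   # VPA family shares a method factor too
  L[5:6, "episodic"] <- sqrt(0.72)   # NIH episodic tests
  L[7:9, "semantic"] <- sqrt(0.48)
  L[10:13, "executive"] <- sqrt(0.052)
  L[10:13, "episodic"] <- sqrt(0.10) # general-axis cross-loading
  L
}

#' Method-factor loadings of the battery
#'
#' Two test-family method factors: one shared by the seven NIH-toolbox
#' tests, one by the three Verbal Paired Associates outcomes. They give the
#' simulated battery the cross-test residual correlation real batteries
#' show, which spreads the scree tail.
#'
#' @return A 13 x 2 numeric matrix.
#' @export
default_method_loadings <- function() {
  tests <- cognitive_battery()
  M <- matrix(0, 13L, 2L, dimnames = list(tests, c("nih_family", "vpa_family")))
  M[c(5, 6, 8, 9, 11, 12, 13), "nih_family"] <- sqrt(0.13)
  M[1:3, "vpa_family"] <- sqrt(0.18)
  M
}

#' Names of the 13 cognitive test variables
#' @return Character vector of length 13.
#' @export
cognitive_battery <- function() {
  c("vpa_immediate_recall", "vpa_delayed_recall", "vpa_delayed_free_recall",
    "associative_recall", "nih_auditory_verbal_learning",
    "nih_picture_sequence_memory",
    "shipley_vocabulary", "nih_picture_vocabulary",
    "nih_oral_reading_recognition",
    "trail_making_task", "nih_flanker", "nih_dimensional_change_card_sort",
    "nih_list_sort_working_memory")
}

#' Map each cognitive test to its domain category
#' @return Named character vector (test -> category).
#' @export
cognitive_category_map <- function() {
  tests <- cognitive_battery()
  stats::setNames(
    rep(c("episodic", "semantic", "executive"), times = c(6L, 3L, 4L)),
    tests)
}

#' Generate synthetic cognitive test scores from latent domain factors
#'
#' Scores are `factors %*% t(loadings) + method_factors %*%
#' t(method_loadings) + noise`, with independent standard-normal factors
#' scaled by `factor_sd`. At the calibrated defaults the downstream PCA
#' recovers the study-like spectrum (dominant episodic axis, semantic and
#' weak executive components, slowly decaying tail) and the scree elbow
#' sits at 3.
#'
#' @param n_subjects Number of subjects.
#' @param loadings 13 x 3 loading matrix of the domain factors (default
#'   [default_cognitive_loadings()]).
#' @param factor_sd Positive standard deviations of the 3 domain factors
#'   (default unit, the calibrated loadings already carry the strengths).
#' @param noise_sd Residual standard deviation: a scalar, a length-13
#'   vector, or `NULL` (default) for the calibrated per-test values that
#'   standardize the default battery to unit variance.
#' @param method_loadings Optional 13 x m loading matrix of test-family
#'   method factors (default [default_method_loadings()]; `NULL` disables
#'   them).
#' @param seed Integer seed.
#' @param factors Optional n_subjects x 3 matrix of domain-factor scores to
#'   use instead of drawing them (method factors and noise still added).
#' @return n_subjects x 13 matrix of scores, columns named by test.
#' @export
gen_cognitive_scores <- function(n_subjects, loadings =
                                   default_cognitive_loadings(),
                                 factor_sd = c(1, 1, 1), noise_sd = NULL,
                                 method_loadings = default_method_loadings(),
                                 seed = 1L, factors = NULL) {
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != 13L || ncol(loadings) != 3L) {
    stop("'loadings' must be a 13 x 3 matrix")
  }
  if (length(factor_sd) != 3L || any(factor_sd <= 0)) {
    stop("'factor_sd' must be 3 positive values")
  }
  if (!is.null(method_loadings)) {
    method_loadings <- as.matrix(method_loadings)
    if (nrow(method_loadings) != 13L) {
      stop("'method_loadings' must have 13 rows")
    }
  }
  communality <- rowSums(loadings^2) +
    if (is.null(method_loadings)) 0 else rowSums(method_loadings^2)
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(pmax(1 - communality, 0))
  }
  if (!length(noise_sd) %in% c(1L, 13L) || any(noise_sd < 0)) {
    stop("'noise_sd' must be a non-negative scalar or length-13 vector")
  }
  noise_sd <- rep_len(noise_sd, 13L)
  set.seed(derive_seed(seed, 17L))
  if (is.null(factors)) {
    factors <- matrix(stats::rnorm(n_subjects * 3L), n_subjects, 3L) %*%
      diag(factor_sd)
  } else {
    factors <- as.matrix(factors)
    if (nrow(factors) != n_subjects || ncol(factors) != 3L) {
      stop("'factors' must be n_subjects x 3")
    }
  }
  scores <- factors %*% t(loadings)
  if (!is.null(method_loadings)) {
    mf <- matrix(stats::rnorm(n_subjects * ncol(method_loadings)),
                 n_subjects, ncol(method_loadings))
    scores <- scores + mf %*% t(method_loadings)
  }
  scores <- scores + vapply(noise_sd, function(s)
    stats::rnorm(n_subjects, sd = s), numeric(n_subjects))
  colnames(scores) <- rownames(loadings) %||% cognitive_battery()
  scores
}

#' Generate outcomes from a linear model with a brain-change x BFR interaction
#'
#' `outcome = intercept + b_bc * bc + b_bfr * bfr + b_int * bc * bfr +
#' b_site * site + b_sex * sex + noise`. Used to give the moderation
#' regressions a known ground truth.
#'
#' @param bc Numeric vector of brain-change values.
#' @param bfr Numeric vector of BFR values in `[0, 1]`, same length.
#' @param site,sex Binary (0/1) covariate vectors, same length.
#' @param betas Named or positional numeric vector
#'   `(b_bc, b_bfr, b_interaction, b_site, b_sex, intercept)`.
#' @param noise_sd Non-negative residual standard deviation.
#' @param seed Integer seed.
#' @return Numeric outcome vector.
#' @export
gen_moderated_outcome <- function(bc, bfr, site, sex, betas, noise_sd,
                                  seed = 1L) {
  n <- length(bc)
  if (length(bfr) != n || length(site) != n || length(sex) != n) {
    stop("predictor vectors must have equal length")
  }
  if (length(betas) != 6L) {
    stop("'betas' must be (b_bc, b_bfr, b_interaction, b_site, b_sex, intercept)")
  }
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  set.seed(derive_seed(seed, 29L))
  betas <- as.numeric(betas)
  betas[6L] + betas[1L] * bc + betas[2L] * bfr + betas[3L] * bc * bfr +
    betas[4L] * site + betas[5L] * sex +
    stats::rnorm(n, sd = noise_sd)
}

#' Generate a complete synthetic cohort
#'
#' Builds a cohort with the statistical structure the full analysis assumes:
#' two sessions of BOLD-like timeseries per subject whose latent state
#' alternation determines a ground-truth redundant-time fraction, a subject
#' table with age-dependent brain-change measures and a right-skewed motion
#' summary, 13 cognitive scores driven by three latent domain factors, and
#' an episodic factor generated from a linear model with a known
#' brain-change x BFR interaction.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Regions per timeseries (default 20; the study-scale
#'   value would be 167).
#' @param n_volumes Volumes per session before any trimming (default 204).
#' @param block_volumes Length of each latent state block (default 50,
#'   matching the analysis window).
#' @param snr Signal-to-noise ratio of the timeseries (default 10).
#' @param betas Generator coefficients for the episodic outcome,
#'   `(b_bc, b_bfr, b_int, b_site, b_sex, intercept)`.
#' @param bfr_age_weight Share of the ground-truth BFR variance driven by
#'   (negative) chronological age, in `[0, 1)` (default 0.5).
#' @param outcome_noise_sd Residual SD of the episodic outcome model.
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: `timeseries` (list of
#'   per-subject lists of two [regional_ts()]), `subjects` (data.frame),
#'   `cognitive_scores` (matrix) and `truth` (generator record).
#' @export
gen_cohort <- function(n_subjects = 40L, n_regions = 20L, n_volumes = 204L,
                       block_volumes = 50L, snr = 10,
                       betas = c(14.39, -0.03, -0.15, -0.74, 1.02, 0),
                       outcome_noise_sd = 1.71, bfr_age_weight = 0.5,
                       seed = 1L) {
  stop_if_not_scalar_count(n_subjects, "n_subjects", min = 2L)
  set.seed(derive_seed(seed, 101L))
  age <- stats::runif(n_subjects, 18, 89)
  sex <- stats::rbinom(n_subjects, 1L, 0.5)
  site <- stats::rbinom(n_subjects, 1L, 0.5)
  # age-linear structural measures with plausible scales
  cortical_thickness <- 2.9 - 0.008 * (age - 18) +
    stats::rnorm(n_subjects, sd = 0.08)
  tiv <- stats::rnorm(n_subjects, 1.5e6, 1.2e5)
  gm_volume <- tiv * (0.38 - 0.0009 * (age - 18) +
                        stats::rnorm(n_subjects, sd = 0.012))
  brain_age <- age + stats::rnorm(n_subjects, sd = 5)
  max_displacement <- stats::rlnorm(n_subjects, meanlog = log(0.8),
                                    sdlog = 0.6)

  # ground-truth redundant-time fraction per subject, partly driven by age
  # (weight bfr_age_weight) so BFR and brain change covary as the moderation
  # analysis expects
  z <- -bfr_age_weight * as.numeric(scale(age)) +
    sqrt(1 - bfr_age_weight^2) * stats::rnorm(n_subjects)
  bfr_true <- pmin(pmax(0.5 + 0.22 * z, 0.02), 0.98)

  analysed <- n_volumes - (n_volumes %% block_volumes)
  n_blocks <- analysed %/% block_volumes
  timeseries <- vector("list", n_subjects)
  state_seqs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sessions <- vector("list", 2L)
    seqs <- vector("list", 2L)
    # allocate round(bfr_true * total blocks) redundant blocks across the
    # two sessions, at seeded random positions, so the realized
    # redundant-time fraction matches the target closely
    set.seed(derive_seed(seed, 1000L + i))
    total_blocks <- 2L * n_blocks
    k_red <- round(bfr_true[i] * total_blocks)
    all_labs <- rep("FRAGILE", total_blocks)
    if (k_red > 0L) all_labs[sample.int(total_blocks, k_red)] <- "REDUNDANT"
    for (s in 1:2) {
      labs <- all_labs[((s - 1L) * n_blocks + 1L):(s * n_blocks)]
      seqs[[s]] <- labs
      ts <- gen_timeseries(n_regions, analysed, state_sequence(labs), snr,
                           seed = derive_seed(seed, 2000L + i * 2L + s),
                           subject_id = sprintf("sub-%03d", i),
                           session_id = as.character(s))
      if (analysed < n_volumes) {
        # prepend dummy initial volumes so the standard trim applies
        pad <- matrix(stats::rnorm((n_volumes - analysed) * n_regions),
                      n_volumes - analysed, n_regions)
        colnames(pad) <- colnames(ts$values)
        ts$values <- rbind(pad, ts$values)
      }
      sessions[[s]] <- ts
    }
    timeseries[[i]] <- sessions
    state_seqs[[i]] <- seqs
  }
  names(timeseries) <- sprintf("sub-%03d", seq_len(n_subjects))
  names(state_seqs) <- names(timeseries)

  # episodic factor from the moderation model; semantic/executive free
  f1 <- gen_moderated_outcome(cortical_thickness, bfr_true, site, sex,
                              betas, outcome_noise_sd,
                              seed = derive_seed(seed, 3L))
  set.seed(derive_seed(seed, 4L))
  f2 <- stats::rnorm(n_subjects, sd = 1.3)
  f3 <- stats::rnorm(n_subjects, sd = 1)
  cognitive_scores <- gen_cognitive_scores(
    n_subjects, seed = derive_seed(seed, 5L),
    factors = cbind(f1 - mean(f1), f2, f3))

  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
    age = age, sex = sex, site = site,
    cortical_thickness = cortical_thickness,
    gm_volume = gm_volume, tiv = tiv, brain_age = brain_age,
    max_displacement = max_displacement,
    bfr_true = bfr_true,
    stringsAsFactors = FALSE)

  structure(
    list(timeseries = timeseries,
         subjects = subjects,
         cognitive_scores = cognitive_scores,
         truth = list(betas = betas, outcome_noise_sd = outcome_noise_sd,
                      bfr_true = bfr_true, state_sequences = state_seqs,
                      snr = snr, block_volumes = block_volumes,
                      seed = seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, 2 sessions of %d volumes x %d regions\n",
    nrow(x$subjects), nrow(x$timeseries[[1]][[1]]$values),
    ncol(x$timeseries[[1]][[1]]$values)))
  invisible(x)
}
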