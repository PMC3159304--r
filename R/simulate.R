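#' Simulation parameters for the repeated-measures group design
#'
#' Describes the generative signal model
#' `value(s in group g, condition t, measure j) =
#'   offset_t + Delta_a[g, j] + P_{s,j} + eps_{s,t,j}`,
#' with a per-subject random effect `P_{s,j} ~ N(0, sigma_p^2)` drawn once
#' per subject and measure (shared across the k conditions — each simulated
#' person's k outcomes reuse the same person deviate) and i.i.d. errors
#' `eps ~ N(0, sigma_e^2)` per cell.  Groups are contiguous blocks of
#' subjects.  Under the null hypothesis all group effects are equal (zero);
#' the fixed condition offsets mimic state effects and are irrelevant to
#' the group test, since both `H` and `E` are computed about cell means.
#'
#' Defaults reproduce the canonical design this package is calibrated for:
#' 2 groups of 15 subjects, `k = 4` conditions, unit person and error
#' variances, condition offsets `{0, 1, 2, 3} * sigma_e`.
#'
#' @param k number of conditions.
#' @param n_groups number of groups.
#' @param subjects_per_group subjects per group (scalar or vector of length
#'   `n_groups`).
#' @param sigma_e error standard deviation(s); scalar or one per measure.
#' @param sigma_p person-effect standard deviation(s); scalar or one per
#'   measure.
#' @param condition_offsets `k` fixed condition offsets (applied to every
#'   measure).
#' @param group_effects fixed group offsets: either a vector of length
#'   `n_groups` (applied to every measure) or an `n_groups x n_measures`
#'   matrix.  All zero under the null.
#' @param n_measures number of measures.
#' @param between_measure_corr correlation of the error deviates across
#'   measures (default 0; person deviates are always independent across
#'   measures).
#' @param rdist univariate sampler `function(n)` for standardized deviates
#'   (default [stats::rnorm()]); any zero-mean unit-variance sampler may be
#'   plugged in — the Monte Carlo calibration does not rely on normality.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(k = 4L, n_groups = 2L,
                              subjects_per_group = 15L,
                              sigma_e = 1, sigma_p = 1,
                              condition_offsets = (seq_len(k) - 1L) *
                                max(sigma_e),
                              group_effects = rep(0, n_groups),
                              n_measures = 1L,
                              between_measure_corr = 0,
                              rdist = stats::rnorm) {
  k <- as.integer(k); n_groups <- as.integer(n_groups)
  n_measures <- as.integer(n_measures)
  subjects_per_group <- rep_len(as.integer(subjects_per_group), n_groups)
  stopifnot(k >= 1L, n_groups >= 2L, all(subjects_per_group >= 2L),
            n_measures >= 1L)
  sigma_e <- rep_len(as.numeric(sigma_e), n_measures)
  sigma_p <- rep_len(as.numeric(sigma_p), n_measures)
  if (any(sigma_e < 0) || any(sigma_p < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  condition_offsets <- as.numeric(condition_offsets)
  if (length(condition_offsets) != k) {
    stop("need exactly k condition offsets", call. = FALSE)
  }
  if (is.matrix(group_effects)) {
    if (!all(dim(group_effects) == c(n_groups, n_measures))) {
      stop("group_effects matrix must be n_groups x n_measures",
           call. = FALSE)
    }
  } else {
    if (length(group_effects) != n_groups) {
      stop("need one group effect per group", call. = FALSE)
    }
    group_effects <- matrix(rep(as.numeric(group_effects), n_measures),
                            nrow = n_groups)
  }
  if (abs(between_measure_corr) > 1) {
    stop("between_measure_corr must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(k = k, n_groups = n_groups,
                 subjects_per_group = subjects_per_group,
                 sigma_e = sigma_e, sigma_p = sigma_p,
                 condition_offsets = condition_offsets,
                 group_effects = group_effects,
                 n_measures = n_measures,
                 between_measure_corr = between_measure_corr,
                 rdist = rdist),
            class = "simulation_params")
}

#' Simulate a feature dataset from the generative signal model
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @return a [feature_dataset()] with subjects `s1, s2, ...` labelled into
#'   groups `g1, g2, ...` in contiguous blocks, conditions `c1, ..., ck`
#'   and measures `v1, ..., vn`.
#' @export
simulate_dataset <- function(params, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- sum(params$subjects_per_group)
  k <- params$k; n <- params$n_measures
  gi <- rep(seq_len(params$n_groups), params$subjects_per_group)
  rdist <- params$rdist

  # person effects: one deviate per subject and measure, shared across k
  P <- matrix(rdist(S * n), nrow = S, ncol = n)
  P <- sweep(P, 2L, params$sigma_p, `*`)

  # errors: i.i.d. per cell, optionally correlated across measures
  Eps <- matrix(rdist(S * k * n), nrow = S * k, ncol = n)
  rho <- params$between_measure_corr
  if (n > 1L && rho != 0) {
    Sig <- matrix(rho, n, n); diag(Sig) <- 1
    Eps <- Eps %*% chol(Sig)
  }
  Eps <- sweep(Eps, 2L, params$sigma_e, `*`)

  values <- array(NA_real_, dim = c(S, k, n),
                  dimnames = list(paste0("s", seq_len(S)),
                                  paste0("c", seq_len(k)),
                                  paste0("v", seq_len(n))))
  for (j in seq_len(n)) {
    base <- matrix(rep(params$condition_offsets, each = S), nrow = S) +
      P[, j] + params$group_effects[gi, j] +
      matrix(Eps[, j], nrow = S, ncol = k)
    values[, , j] <- base
  }
  group <- stats::setNames(paste0("g", gi), paste0("s", seq_len(S)))
  new_feature_dataset(values, group)
}
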