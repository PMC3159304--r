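#' The F-ratio test-statistic family
#'
#' Four statistics built from the jackknife F-ratio
#' `R = sigma^2(F) / (4 <F>^2)` of [resample_f()].  Small values of
#' `teststat0`/`teststat1` signal a fixed (non-random) group effect; the
#' normalized forms `teststat1R`/`teststat1M` have null expectation 1 and
#' deviate upward when one variable carries a fixed effect the joint
#' multivariate statistic has already absorbed.  All four are calibrated
#' against Monte Carlo null distributions ([build_null_distribution()]),
#' never against analytic F tables.
#'
#' `teststat0` pools the per-measure univariate F resampling summaries:
#' `sum_i sigma^2(F_i) / (4 (sum_i <F_i>)^2)`.
#'
#' `teststat1` replaces the univariate F values by their contributions to
#' the df-adjusted eigenvalues of `H E^-1` (see [eigen_contributions()]),
#' weighting eigendirection `i` by `1/g_i` according to the `stattype`
#' (for Hotelling all `g_i` are equal, and the statistic is the `s = 1`
#' form applied to the combined F; only relative `g_i` matter since common
#' factors cancel in the ratio).
#'
#' `teststat1R` divides `teststat1` by the multivariate ratio
#' `sigma^2(F_multi) / (4 <F_multi>^2)` computed on the same splittings;
#' its null expectation is 1.
#'
#' `teststat1M` is the incremental version: a carried-over F value `F_c`
#' (from `n_c` measures already accepted as showing an effect) is combined
#' with a candidate measure's univariate summary,
#' `[n_c^2 var(F_c) + sigma^2(F_add)] / (4 (n_c F_c + <F_add>)^2)`,
#' normalized by the multivariate ratio.
#'
#' @param rs a `resample_summary` from [resample_f()] with
#'   `per_measure = TRUE`.
#' @param measures optional subset of measure names to pool (default: all).
#' @return an object of class `teststat_result`: list with `name`, `value`,
#'   `df_eff`, and `components` (the per-term variances and mean F values
#'   entering the statistic).
#' @name teststats
NULL

new_teststat <- function(name, value, df_eff, components) {
  structure(list(name = name, value = value, df_eff = df_eff,
                 components = components),
            class = "teststat_result")
}

#' @export
print.teststat_result <- function(x, ...) {
  cat(sprintf("%s = %.6g (df_eff = %.4g)\n", x$name, x$value, x$df_eff))
  invisible(x)
}

pm_summaries <- function(rs, measures = NULL) {
  if (is.null(rs$per_measure)) {
    stop("resample summary lacks per-measure univariate summaries; rerun ",
         "resample_f() with per_measure = TRUE", call. = FALSE)
  }
  pm <- rs$per_measure
  if (!is.null(measures)) {
    unknown <- setdiff(measures, names(pm))
    if (length(unknown)) stop("unknown measure(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    pm <- pm[measures]
  }
  pm
}

#' @rdname teststats
#' @export
teststat0 <- function(rs, measures = NULL) {
  pm <- pm_summaries(rs, measures)
  vars <- vapply(pm, `[[`, numeric(1L), "f_var")
  means <- vapply(pm, `[[`, numeric(1L), "f_mean")
  if (sum(means) == 0) {
    stop("undefined statistic: sum of mean F values is zero", call. = FALSE)
  }
  new_teststat("teststat0",
               value = sum(vars) / (4 * sum(means)^2),
               df_eff = effective_df(vars, rep(1, length(vars))),
               components = list(f_var = vars, f_mean = means))
}

# 1/g_i weights (up to an irrelevant common factor) chosen so that
# sum_i (1/g_i) c_i df_e/df_h reproduces the stattype's full-sample F.
stattype_inv_g <- function(cv, s, stattype) {
  switch(stattype,
         hotelling = rep(1 / s, s),
         pillai = {
           P <- sum(cv / (1 + cv))
           1 / ((1 + cv) * (s - P))
         },
         roy = c(1, rep(0, s - 1L)))
}

#' @rdname teststats
#' @param contributions an `s x n` contribution matrix from
#'   [eigen_contributions()]; computed from the full-sample decomposition
#'   in `rs` when `NULL`.  Contributions are held fixed across splittings.
#' @param stattype statistic type for the eigendirection weights `g_i`
#'   (default: the `stattype` of `rs`).
#' @export
teststat1 <- function(rs, contributions = NULL, stattype = rs$stattype) {
  stattype <- match.arg(stattype, c("hotelling", "pillai", "roy"))
  if (is.null(contributions)) contributions <- eigen_contributions(rs$full)
  K <- contributions
  if (is.null(rs$f_matrix)) {
    stop("resample summary lacks the per-measure F matrix; rerun ",
         "resample_f() with per_measure = TRUE", call. = FALSE)
  }
  Fmat <- rs$f_matrix[, colnames(K), drop = FALSE]   # m x n
  s <- nrow(K)
  cv <- rs$full$eigenvalues[seq_len(s)]
  inv_g <- stattype_inv_g(cv, s, stattype)
  # per-splitting eigendirection terms y[t, i] = (1/g_i) sum_j K[i, j] F[t, j]
  Y <- Fmat %*% t(K * inv_g)                          # m x s
  vars <- apply(Y, 2L, stats::var)
  means <- colMeans(Y)
  keep <- inv_g > 0
  if (sum(means[keep]) == 0) {
    stop("undefined statistic: combined mean F is zero", call. = FALSE)
  }
  # df_eff over the per-measure resampling variances (spans [1, n], as the
  # per-direction terms built from a single contribution matrix would not)
  pm_vars <- apply(Fmat, 2L, stats::var)
  new_teststat("teststat1",
               value = sum(vars[keep]) / (4 * sum(means[keep])^2),
               df_eff = effective_df(pm_vars, rep(1, length(pm_vars))),
               components = list(term_var = vars, term_mean = means,
                                 inv_g = inv_g))
}

#' @rdname teststats
#' @export
teststat1R <- function(rs, contributions = NULL, stattype = rs$stattype) {
  if (rs$f_var == 0) {
    stop("degenerate multivariate ratio: sigma^2(F_multi) = 0 ",
         "(p = 1 splittings?)", call. = FALSE)
  }
  t1 <- teststat1(rs, contributions, stattype)
  new_teststat("teststat1R",
               value = t1$value / rs$ratio,
               df_eff = t1$df_eff,
               components = c(t1$components,
                              list(multi_ratio = rs$ratio)))
}

#' @rdname teststats
#' @param F_c carried-over F value of the already-accepted measures.
#' @param var_F_c resampling variance of the carried-over F.
#' @param n_c number of carried measures (`k` in the incremental formula).
#' @param add univariate resampling summary (list with `f_mean`, `f_var`)
#'   of the candidate measure.
#' @param multi multivariate resampling summary (list with `f_mean`,
#'   `f_var`), typically the top level of `rs`.
#' @export
teststat1M <- function(F_c, var_F_c, n_c, add, multi) {
  if (!(F_c > 0)) stop("carried-over F_c must be positive", call. = FALSE)
  if (n_c < 1L) stop("need n_c >= 1 carried measures", call. = FALSE)
  denom_obs <- 4 * (n_c * F_c + add$f_mean)^2
  multi_ratio <- multi$f_var / (4 * multi$f_mean^2)
  if (denom_obs == 0 || multi_ratio == 0) {
    stop("degenerate denominator in teststat1M", call. = FALSE)
  }
  value <- ((n_c^2 * var_F_c + add$f_var) / denom_obs) / multi_ratio
  new_teststat("teststat1M",
               value = value,
               df_eff = effective_df(c(var_F_c, add$f_var), c(n_c, 1)),
               components = list(F_c = F_c, var_F_c = var_F_c, n_c = n_c,
                                 f_mean_add = add$f_mean,
                                 f_var_add = add$f_var,
                                 multi_ratio = multi_ratio))
}

#' Incremental statistic from one resampling summary
#'
#' Convenience wrapper deriving the carried-over quantities of
#' [teststat1M()] from the per-measure summaries of a single
#' [resample_f()] run: the carried F per splitting is the mean of the
#' carried measures' univariate F values (the trace picture for a
#' rank-one effect), and the candidate contributes its own summary.
#'
#' @param rs a `resample_summary` with per-measure summaries.
#' @param carried character vector of carried measure names.
#' @param candidate the candidate measure name.
#' @return a `teststat_result` of name `teststat1M`.
#' @export
teststat1M_from_summary <- function(rs, carried, candidate) {
  pm <- pm_summaries(rs, c(carried, candidate))
  n_c <- length(carried)
  Fc_t <- rowMeans(rs$f_matrix[, carried, drop = FALSE])
  teststat1M(F_c = mean(Fc_t), var_F_c = stats::var(Fc_t), n_c = n_c,
             add = pm[[candidate]],
             multi = list(f_mean = rs$f_mean, f_var = rs$f_var))
}

#' Effective degrees of freedom of pooled variances
#'
#' Welch–Satterthwaite form `(sum sigma_i^2)^2 / sum(sigma_i^4 / df_i)`:
#' minimized (at the smallest contributing df) when one variance term
#' dominates, maximized (at `sum df_i`) for equal contributions.
#'
#' @param variances non-negative variance terms, at least one positive.
#' @param dfs degrees of freedom of each term (>= 1).
#' @return the effective degrees of freedom, a scalar in
#'   `[min df, sum(dfs)]`.
#' @export
effective_df <- function(variances, dfs = rep(1, length(variances))) {
  stopifnot(length(variances) == length(dfs))
  if (any(variances < 0) || any(dfs < 1)) {
    stop("need variances >= 0 and dfs >= 1", call. = FALSE)
  }
  if (all(variances == 0)) {
    stop("effective degrees of freedom undefined for all-zero variances",
         call. = FALSE)
  }
  sum(variances)^2 / sum(variances^2 / dfs)
}

#' Invert the null expectation of the F-ratio for nu
#'
#' The ratio `nu` measures the random share of the effect term:
#' `nu = 1` for a pure random effect, `nu < 1` flags a fixed effect.  The
#' normalized ratio satisfies `E[R] = nu^2 / (2 df_k) + 1 / (2 df_ek)`
#' under the error-propagation approximation, giving the inversion
#' `nu = sqrt(max(0, 2 df_k (R - 1 / (2 df_ek))))` (clamped at 0).
#'
#' @param ratio observed normalized ratio `R = sigma^2(F) / (4 <F>^2)`,
#'   >= 0.
#' @param df_k effect degrees of freedom.
#' @param df_ek error degrees of freedom.
#' @return a list of class `nu_estimate` with `nu`, `df_k`, `df_ek`.
#' @export
estimate_nu <- function(ratio, df_k, df_ek) {
  if (ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  nu <- sqrt(max(0, 2 * df_k * (ratio - 1 / (2 * df_ek))))
  structure(list(nu = nu, df_k = df_k, df_ek = df_ek),
            class = "nu_estimate")
}

#' @export
print.nu_estimate <- function(x, ...) {
  cat(sprintf("nu = %.5g (df_k = %g, df_ek = %g); nu < 1 flags a fixed ",
              x$nu, x$df_k, x$df_ek), "effect\n", sep = "")
  invisible(x)
}
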