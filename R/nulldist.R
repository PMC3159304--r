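#' Monte Carlo null distribution of an F-ratio statistic
#'
#' Generates `L` independent datasets under the null hypothesis (no fixed
#' group effect), pushes each through [resample_f()] with the given
#' `(m, p, stattype)` and evaluates the requested statistic, yielding a
#' population of `L` null deviates from which empirical quantiles and
#' p-values are read off.  Because the observed statistic and the null
#' deviates are produced by the identical resampling procedure with
#' identical `(m, p, group sizes)`, the unknown subsampling factor on
#' `sigma^2(F)` cancels from the comparison — the central calibration
#' argument of the method.
#'
#' Available statistics: `"ratio"` (the univariate or multivariate
#' normalized ratio `sigma^2(F) / (4 <F>^2)` itself), `"teststat0"`,
#' `"teststat1"`, `"teststat1R"`, `"teststat1M"` (carried set = all
#' measures but the last, candidate = last measure).
#'
#' @param params a [simulation_params()] whose group effects are all equal
#'   (the generator must satisfy the null).
#' @param statistic statistic name, see Details.
#' @param m,p,stattype resampling settings, see [resample_f()].
#' @param L number of Monte Carlo replicates (>= 20).
#' @param seed integer seed; the run is fully reproducible from it.
#' @return an object of class `null_distribution`: list with `deviates`
#'   (length `L`), `df_eff` (paired effective dfs, `NA` for `"ratio"`),
#'   `statistic`, `params`, `m`, `p`, `stattype`, `L`, `seed`, `fit`
#'   (slot for a [quantile_vs_dfeff()] fit, initially `NULL`).
#' @export
build_null_distribution <- function(params, statistic = "ratio",
                                    m = 30L, p = 2 / 3,
                                    stattype = c("hotelling", "pillai",
                                                 "roy"),
                                    L = 100L, seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  stattype <- match.arg(stattype)
  statistic <- match.arg(statistic, c("ratio", "teststat0", "teststat1",
                                      "teststat1R", "teststat1M"))
  L <- as.integer(L)
  if (L < 20L) stop("need L >= 20 Monte Carlo replicates", call. = FALSE)
  ge <- params$group_effects
  if (any(abs(sweep(ge, 2L, ge[1L, ])) > 0)) {
    stop("null distribution requires equal group effects in the generator ",
         "(H0 must hold)", call. = FALSE)
  }
  if (statistic %in% c("teststat1M") && params$n_measures < 2L) {
    stop("teststat1M needs at least 2 measures (carried + candidate)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 4L, L)
  deviates <- numeric(L)
  df_eff <- rep(NA_real_, L)
  for (r in seq_len(L)) {
    res <- NULL
    for (attempt in 0:3) {
      res <- tryCatch(
        null_replicate(params, statistic, m, p, stattype,
                       sub_seeds[r] + attempt),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value)) break
    }
    if (is.null(res) || !is.finite(res$value)) {
      stop("Monte Carlo replicate ", r, " failed after 4 attempts",
           call. = FALSE)
    }
    deviates[r] <- res$value
    df_eff[r] <- res$df_eff
  }
  structure(list(deviates = deviates, df_eff = df_eff,
                 statistic = statistic, params = params,
                 m = as.integer(m), p = p, stattype = stattype, L = L,
                 seed = as.integer(seed), fit = NULL),
            class = "null_distribution")
}

null_replicate <- function(params, statistic, m, p, stattype, seed) {
  set.seed(as.integer(seed))
  fd <- simulate_dataset(params, seed = NULL)
  rs <- resample_f(fd, m = m, p = p, stattype = stattype, seed = NULL)
  evaluate_statistic(rs, statistic)
}

# Evaluate a named statistic on a resample_summary.
evaluate_statistic <- function(rs, statistic) {
  switch(statistic,
         ratio = list(value = rs$ratio, df_eff = NA_real_),
         teststat0 = {
           t0 <- teststat0(rs)
           list(value = t0$value, df_eff = t0$df_eff)
         },
         teststat1 = {
           t1 <- teststat1(rs)
           list(value = t1$value, df_eff = t1$df_eff)
         },
         teststat1R = {
           t1r <- teststat1R(rs)
           list(value = t1r$value, df_eff = t1r$df_eff)
         },
         teststat1M = {
           nms <- names(rs$per_measure)
           tm <- teststat1M_from_summary(
             rs, carried = nms[-length(nms)],
             candidate = nms[length(nms)])
           list(value = tm$value, df_eff = tm$df_eff)
         },
         stop("unknown statistic: ", statistic, call. = FALSE))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte Carlo null distribution of %s: L = %d replicates\n",
              x$statistic, x$L))
  cat(sprintf("  settings: m = %d, p = %.3g, stattype = %s, seed = %d\n",
              x$m, x$p, x$stattype, x$seed))
  qs <- stats::quantile(x$deviates, c(0.05, 0.5, 0.95))
  cat(sprintf("  deviates: mean = %.4g, 5%% = %.4g, median = %.4g, ",
              mean(x$deviates), qs[1L], qs[2L]),
      sprintf("95%% = %.4g\n", qs[3L]), sep = "")
  invisible(x)
}

#' Rank-order empirical quantile of a null distribution
#'
#' The `ceiling(P * L)`-th smallest deviate.  Rejection is on the low
#' tail: an observed ratio below the `P` quantile occurs by chance with
#' probability at most `P` under the null.
#'
#' @param nd a `null_distribution`.
#' @param P probability in (0, 1).
#' @return the quantile value.
#' @export
empirical_quantile <- function(nd, P) {
  if (!(P > 0 && P < 1)) stop("P must lie in (0, 1)", call. = FALSE)
  sort(nd$deviates)[ceiling(P * nd$L)]
}

#' Linear dependence of a null quantile on effective degrees of freedom
#'
#' Bins the null replicates by their effective degrees of freedom, takes
#' the empirical `P` quantile within each bin and fits
#' `quantile_P = a_P + b_P * df_eff` by least squares.  Used to adjust the
#' null distribution to the observed `df_eff` instead of waiting for
#' replicates with matching `df_eff` to emerge by chance.
#'
#' @param nd a `null_distribution` whose `df_eff` values are present with
#'   positive spread.
#' @param P quantile probability in (0, 1).
#' @param bins number of (equal-count) bins.
#' @return an object of class `dfeff_fit`: list with `a`, `b`, `P`,
#'   `bin_df` (mean df_eff per bin), `bin_q` (quantile per bin), and
#'   `predict` (function of df_eff).
#' @export
quantile_vs_dfeff <- function(nd, P = 0.05, bins = 5L) {
  if (!(P > 0 && P < 1)) stop("P must lie in (0, 1)", call. = FALSE)
  d <- nd$df_eff
  if (all(is.na(d))) {
    stop("null distribution carries no effective degrees of freedom",
         call. = FALSE)
  }
  if (max(d) - min(d) <= 0) {
    warning("all df_eff identical: fit degenerate, slope set to 0",
            call. = FALSE)
    q <- sort(nd$deviates)[ceiling(P * nd$L)]
    return(structure(list(a = q, b = 0, P = P, bin_df = d[1L], bin_q = q,
                          predict = function(df_eff) rep(q,
                                                         length(df_eff))),
                     class = "dfeff_fit"))
  }
  bins <- max(2L, min(as.integer(bins), floor(nd$L / 4L)))
  ord <- order(d)
  grp <- cut(seq_along(ord), breaks = bins, labels = FALSE)
  bin_df <- tapply(d[ord], grp, mean)
  bin_q <- tapply(nd$deviates[ord], grp, function(v)
    sort(v)[ceiling(P * length(v))])
  fit <- stats::lm.fit(cbind(1, as.numeric(bin_df)), as.numeric(bin_q))
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  structure(list(a = unname(a), b = unname(b), P = P,
                 bin_df = as.numeric(bin_df), bin_q = as.numeric(bin_q),
                 predict = function(df_eff) unname(a + b * df_eff)),
            class = "dfeff_fit")
}

#' @export
print.dfeff_fit <- function(x, ...) {
  cat(sprintf("Quantile-vs-df_eff fit at P = %.3g: q = %.5g + %.5g * ",
              x$P, x$a, x$b), "df_eff\n", sep = "")
  invisible(x)
}

#' Monte Carlo p-value of an observed statistic
#'
#' Lower-tail add-one rule `(r + 1) / (L + 1)` where `r` counts the null
#' deviates at or below the observed value: the probability that a ratio as small
#' or smaller occurs by chance under the null.  The resolution floor is
#' `1 / (L + 1)`.  When `df_eff` and a [quantile_vs_dfeff()] fit are
#' supplied, each deviate is first level-adjusted to the observed
#' `df_eff` along the fitted slope.
#'
#' @param nd a `null_distribution`.
#' @param observed observed statistic value (finite).
#' @param df_eff optional observed effective degrees of freedom.
#' @param fit optional `dfeff_fit`; defaults to `nd$fit` if present.
#' @return the Monte Carlo p-value in `(0, 1]`.
#' @export
p_value <- function(nd, observed, df_eff = NULL, fit = nd$fit) {
  if (!is.finite(observed)) stop("observed value must be finite",
                                 call. = FALSE)
  dev <- nd$deviates
  if (!is.null(df_eff) && !is.null(fit)) {
    dev <- dev + fit$b * (df_eff - nd$df_eff)
  }
  (sum(dev <= observed) + 1) / (nd$L + 1)
}

#' Compare the F-ratio test with the classical mixed-model test
#'
#' Simulates `n_datasets` univariate datasets from `params` (typically
#' with a fixed group effect present, so the null is false), computes for
#' each (i) the classical mixed-model tail probability
#' ([classical_mixed_f()]) and (ii) the Monte Carlo p-value of the
#' normalized resampling ratio against a null distribution generated once
#' under the matching no-effect hypothesis, and summarizes the per-dataset
#' differences `Delta P = P_classical - P_fratio`.  A positive majority of
#' `Delta P` means the F-ratio test assigns smaller chance probabilities
#' to the same data, i.e. is the more sensitive test.  Asymmetry is
#' assessed by a one-degree-of-freedom goodness-of-fit statistic of the
#' sign counts against 50/50.
#'
#' @param params a [simulation_params()] with `n_measures = 1`; group
#'   effects may be nonzero (the scenario under test).
#' @param n_datasets number of scenario datasets.
#' @param m,p resampling settings.
#' @param L size of the shared Monte Carlo null distribution.
#' @param seed integer seed.
#' @return an object of class `comparison_result`: list with `delta_p`,
#'   `p_classical`, `p_fratio`, and `summary` (list with `n_pos`, `n_neg`,
#'   `n_zero`, `chisq`, `p.value`).
#' @export
compare_with_classical <- function(params, n_datasets = 100L, m = 30L,
                                   p = 2 / 3, L = 100L, seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$n_measures != 1L) {
    stop("the comparison study is univariate: use n_measures = 1",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 4L, n_datasets + 1L)
  null_params <- params
  null_params$group_effects[] <- 0
  nd <- build_null_distribution(null_params, statistic = "ratio", m = m,
                                p = p, L = L, seed = seeds[1L])
  p_cl <- p_fr <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    set.seed(seeds[i + 1L])
    fd <- simulate_dataset(params, seed = NULL)
    p_cl[i] <- classical_mixed_f(fd)$p.value
    rs <- resample_f(fd, m = m, p = p, seed = NULL)
    p_fr[i] <- p_value(nd, rs$ratio)
  }
  dp <- p_cl - p_fr
  n_pos <- sum(dp > 0); n_neg <- sum(dp < 0); n_zero <- sum(dp == 0)
  chisq <- if (n_pos + n_neg > 0) (n_pos - n_neg)^2 / (n_pos + n_neg)
           else 0
  structure(list(delta_p = dp, p_classical = p_cl, p_fratio = p_fr,
                 summary = list(
                   n_pos = n_pos, n_neg = n_neg, n_zero = n_zero,
                   chisq = chisq,
                   p.value = stats::pchisq(chisq, df = 1L,
                                           lower.tail = FALSE))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$summary
  cat("Classical vs. F-ratio comparison over", length(x$delta_p),
      "datasets\n")
  cat(sprintf("  Delta P = P_classical - P_fratio: %d > 0, %d < 0, %d = 0\n",
              s$n_pos, s$n_neg, s$n_zero))
  cat(sprintf("  sign asymmetry: chi^2(1) = %.3g, p = %.4g\n",
              s$chisq, s$p.value))
  invisible(x)
}
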