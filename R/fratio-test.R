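#' Fit an F-ratio test to a feature dataset
#'
#' The package's main entry point.  Resamples the chosen F statistic over
#' `m` random subject subsets ([resample_f()]), evaluates the requested
#' F-ratio statistic, builds a Monte Carlo null distribution with
#' variance components estimated from the data itself (per measure, via
#' [estimate_variance_components()]) and the identical resampling
#' settings, and reports the lower-tail Monte Carlo p-value: the
#' probability that a ratio as small or smaller arises when the group
#' effect is purely random.  For `teststat1R`/`teststat1M`, whose
#' rejection side is the upper tail (values above 1 flag a fixed effect
#' in a single variable), the reported p-value is the upper-tail
#' analogue.
#'
#' @param fd a [feature_dataset()] (or long data.frame coercible by
#'   [feature_dataset()]).
#' @param statistic one of `"ratio"`, `"teststat0"`, `"teststat1"`,
#'   `"teststat1R"`, `"teststat1M"`.  Defaults to `"ratio"` for a single
#'   measure and `"teststat1R"` otherwise.
#' @param m,p,stattype resampling settings, see [resample_f()].
#' @param L Monte Carlo null size.
#' @param seed integer seed for both the observed resampling and the null
#'   generation.
#' @param null_params optional [simulation_params()] for the null
#'   generator; when `NULL`, sample sizes come from the data and per-
#'   measure `sigma_e`/`sigma_p` are estimated from it (condition offsets
#'   are irrelevant to the statistic and set to 0).
#' @param classical also run the univariate classical mixed-model test on
#'   each measure (default `TRUE`).
#' @return an object of class `fratio_test` with `print()` and
#'   `summary()` methods: list with `statistic`, `observed`
#'   (`teststat_result`), `resample` (`resample_summary`), `null`
#'   (`null_distribution`), `p.value`, `nu` (univariate `nu_estimate`s per
#'   measure), `classical` (per-measure [classical_mixed_f()] results),
#'   `call`.
#' @examples
#' params <- simulation_params(n_measures = 2, subjects_per_group = 10)
#' fd <- simulate_dataset(params, seed = 42)
#' ft <- fratio_test(fd, m = 15, L = 30, seed = 1)
#' ft
#' @export
fratio_test <- function(fd, statistic = NULL, m = 30L, p = 2 / 3,
                        stattype = c("hotelling", "pillai", "roy"),
                        L = 100L, seed = 1L, null_params = NULL,
                        classical = TRUE) {
  if (is.data.frame(fd)) fd <- feature_dataset(fd)
  validate_feature_dataset(fd)
  stattype <- match.arg(stattype)
  if (is.null(statistic)) {
    statistic <- if (length(fd$measures) == 1L) "ratio" else "teststat1R"
  }
  statistic <- match.arg(statistic, c("ratio", "teststat0", "teststat1",
                                      "teststat1R", "teststat1M"))
  cl <- match.call()
  seed <- as.integer(seed)

  rs <- resample_f(fd, m = m, p = p, stattype = stattype, seed = seed)
  obs <- evaluate_statistic(rs, statistic)

  if (is.null(null_params)) {
    vc <- lapply(fd$measures, function(ms)
      estimate_variance_components(fd, ms))
    null_params <- simulation_params(
      k = length(fd$conditions),
      n_groups = length(unique(fd$group)),
      subjects_per_group = as.integer(table(factor(fd$group,
                                                   unique(fd$group)))),
      sigma_e = sqrt(vapply(vc, `[[`, numeric(1L), "sigma_e2")),
      sigma_p = sqrt(vapply(vc, `[[`, numeric(1L), "sigma_p2")),
      condition_offsets = rep(0, length(fd$conditions)),
      n_measures = length(fd$measures))
  }
  nd <- build_null_distribution(null_params, statistic = statistic,
                                m = m, p = p, stattype = stattype,
                                L = L, seed = seed + 1L)
  upper_tail <- statistic %in% c("teststat1R", "teststat1M")
  pv <- if (upper_tail) {
    (sum(nd$deviates >= obs$value) + 1) / (nd$L + 1)
  } else {
    p_value(nd, obs$value)
  }

  nu <- lapply(fd$measures, function(ms) {
    estimate_nu(rs$per_measure[[ms]]$ratio, df_k = rs$df_k,
                df_ek = rs$df_ek)
  })
  names(nu) <- fd$measures
  cf <- NULL
  if (classical) {
    cf <- lapply(fd$measures, function(ms) classical_mixed_f(fd, ms))
    names(cf) <- fd$measures
  }

  structure(list(statistic = statistic,
                 observed = new_teststat(statistic, obs$value, obs$df_eff,
                                         components = NULL),
                 resample = rs, null = nd, p.value = pv,
                 tail = if (upper_tail) "upper" else "lower",
                 nu = nu, classical = cf, null_params = null_params,
                 call = cl),
            class = "fratio_test")
}

#' @export
print.fratio_test <- function(x, ...) {
  cat("F-ratio test (", x$statistic, ", ", x$resample$stattype,
      " stattype)\n", sep = "")
  cat(sprintf("  m = %d splittings at p = %.3g; Monte Carlo null L = %d\n",
              x$resample$m, x$resample$p, x$null$L))
  cat(sprintf("  <F> = %.5g, sigma^2(F) = %.5g, ratio = %.5g\n",
              x$resample$f_mean, x$resample$f_var, x$resample$ratio))
  dfe <- x$observed$df_eff
  cat(sprintf("  observed %s = %.5g%s\n", x$statistic, x$observed$value,
              if (is.finite(dfe)) sprintf(" (df_eff = %.4g)", dfe) else ""))
  cat(sprintf("  Monte Carlo p-value (%s tail) = %.4g\n", x$tail,
              x$p.value))
  invisible(x)
}

#' @export
summary.fratio_test <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-measure detail:\n")
  for (nm in names(x$resample$per_measure)) {
    s <- x$resample$per_measure[[nm]]
    line <- sprintf("  %-12s <F> = %8.4g  ratio = %8.4g  nu = %.3f",
                    nm, s$f_mean, s$ratio, x$nu[[nm]]$nu)
    if (!is.null(x$classical)) {
      line <- paste0(line, sprintf("  classical p = %.4g",
                                   x$classical[[nm]]$p.value))
    }
    cat(line, "\n")
  }
  cat(sprintf("\nNull distribution (%s): mean = %.4g, 5%% quantile = %.4g\n",
              x$null$statistic, mean(x$null$deviates),
              empirical_quantile(x$null, 0.05)))
  invisible(x)
}
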