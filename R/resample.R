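#' Delete-d jackknife resampling of the F statistic
#'
#' Repeatedly (`m` times) draws a random subset containing an equal
#' fraction `p` of the subjects of every group (without replacement within
#' a splitting, independently across splittings), keeps all their
#' conditions, and recomputes the multivariate F of the chosen `stattype`
#' on each subset, together with every per-measure univariate F on the same
#' subsets.  The spread of the subset F values estimates `sigma^2(F)`, the
#' sample-to-sample variance of F, up to a subsampling factor that depends
#' on (`m`, `p`, group sizes) only — the factor cancels when the observed
#' ratio is compared with a Monte Carlo null generated with identical
#' settings, which is how inference is done throughout this package.
#'
#' The central normalized quantity is the F-ratio
#' `R = sigma^2(F) / (4 <F>^2)`, whose null (pure random effect)
#' expectation is `1 / (2 df_k) + 1 / (2 df_ek)`; a value well below the
#' null quantiles signals a fixed effect, whose stability across subsets
#' suppresses the variance of F.
#'
#' @param fd a [feature_dataset()] with >= 2 groups.
#' @param m number of random splittings (>= 2; typically 12–50).
#' @param p fraction of each group's subjects entering one splitting; the
#'   per-group subset size is `round(p * n_g)` (round-half-to-even).
#'   `p = 1` is allowed but degenerate (all subset F values coincide) and
#'   triggers a warning.
#' @param stattype multivariate statistic, see [manova_f()].
#' @param seed integer seed; subset draws are a deterministic function of
#'   `(seed, splitting index)`.
#' @param per_measure if `TRUE` (default), also summarize each measure's
#'   univariate F over the same `m` subsets.
#' @return an object of class `resample_summary`: list with `f_values`
#'   (length `m`), `f_mean`, `f_var` (denominator `m - 1`), `ratio`
#'   (`f_var / (4 f_mean^2)`), `m`, `p`, `stattype`, `seed`,
#'   `per_measure` (named list of per-measure summaries, each with
#'   `f_values`, `f_mean`, `f_var`, `ratio`), `f_matrix` (`m x n` matrix of
#'   the per-measure subset F values), `full` (full-sample
#'   `effect_decomposition`), `df_k`/`df_ek` (full-sample effect and error
#'   degrees of freedom), and `df_e_sub` (subset error df).
#' @export
resample_f <- function(fd, m = 30L, p = 2 / 3,
                       stattype = c("hotelling", "pillai", "roy"),
                       seed = NULL, per_measure = TRUE) {
  validate_feature_dataset(fd)
  stattype <- match.arg(stattype)
  m <- as.integer(m)
  if (m < 2L) stop("need m >= 2 splittings", call. = FALSE)
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]", call. = FALSE)

  grp <- factor(fd$group, levels = unique(fd$group))
  G <- nlevels(grp)
  idx_by_group <- split(seq_along(fd$subjects), grp)
  n_g <- lengths(idx_by_group)
  take <- round(p * n_g)           # round-half-to-even, per group
  if (any(take < 2L)) {
    stop("subset too small: round(p * group size) must be >= 2 for every ",
         "group", call. = FALSE)
  }
  k <- length(fd$conditions)
  n_obs_sub <- sum(take) * k
  if (n_obs_sub - G * k < 1L) {
    stop("subset too small for positive error degrees of freedom",
         call. = FALSE)
  }
  if (all(take == n_g)) {
    warning("p = 1: every splitting is the full sample, sigma^2(F) is ",
            "degenerate (0)", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(fd$measures)
  f_multi <- numeric(m)
  f_mat <- matrix(NA_real_, nrow = m, ncol = n,
                  dimnames = list(NULL, fd$measures))
  gi_full <- as.integer(grp)
  for (t in seq_len(m)) {
    sel <- unlist(lapply(seq_len(G), function(g) {
      ii <- idx_by_group[[g]]
      if (take[g] == length(ii)) ii else sample(ii, take[g])
    }), use.names = FALSE)
    dec <- sscp_core(fd$values[sel, , , drop = FALSE], gi_full[sel])
    f_multi[t] <- if (dec$s >= 1L) {
      manova_f_value(dec$eigenvalues[seq_len(dec$s)], dec$s,
                     dec$df_h, dec$df_e, stattype)
    } else 0
    if (per_measure) f_mat[t, ] <- dec$F_univ
  }

  full <- manova_decompose(fd)
  pm <- NULL
  if (per_measure) {
    pm <- lapply(seq_len(n), function(j) summarize_f(f_mat[, j]))
    names(pm) <- fd$measures
  }
  out <- c(summarize_f(f_multi),
           list(m = m, p = p, stattype = stattype,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                per_measure = pm,
                f_matrix = if (per_measure) f_mat else NULL,
                full = full, df_k = full$df_h, df_ek = full$df_e,
                df_e_sub = n_obs_sub - G * k))
  class(out) <- "resample_summary"
  out
}

# Eq.-(14)/(15)-style summary of a set of subset F values.
summarize_f <- function(f_values) {
  f_mean <- mean(f_values)
  f_var <- stats::var(f_values)
  list(f_values = f_values, f_mean = f_mean, f_var = f_var,
       ratio = f_var / (4 * f_mean^2))
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf(
    "F resampling (%s): m = %d splittings at p = %.3g\n", x$stattype,
    x$m, x$p))
  cat(sprintf("  <F> = %.5g, sigma^2(F) = %.5g, ratio = %.5g\n",
              x$f_mean, x$f_var, x$ratio))
  if (!is.null(x$per_measure)) {
    for (nm in names(x$per_measure)) {
      s <- x$per_measure[[nm]]
      cat(sprintf("  %-12s <F> = %.5g, sigma^2(F) = %.5g, ratio = %.5g\n",
                  nm, s$f_mean, s$f_var, s$ratio))
    }
  }
  invisible(x)
}

#' Serialize resampling and test-statistic results to JSON
#'
#' @param x a `resample_summary`, `teststat_result` or `null_distribution`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
fratio_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "resample_summary")) {
    list(type = "resample_summary", m = x$m, p = x$p, stattype = x$stattype,
         seed = x$seed, f_values = x$f_values, f_mean = x$f_mean,
         f_var = x$f_var, ratio = x$ratio,
         per_measure = lapply(x$per_measure, function(s)
           list(f_mean = s$f_mean, f_var = s$f_var, ratio = s$ratio)))
  } else if (inherits(x, "teststat_result")) {
    list(type = "teststat_result", name = x$name, value = x$value,
         df_eff = x$df_eff, components = x$components)
  } else if (inherits(x, "null_distribution")) {
    list(type = "null_distribution", statistic = x$statistic, L = x$L,
         m = x$m, p = x$p, stattype = x$stattype, seed = x$seed,
         params = unclass(x$params), deviates = x$deviates,
         df_eff = x$df_eff)
  } else {
    stop("unsupported object for JSON serialization", call. = FALSE)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
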