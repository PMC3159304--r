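#' Between-group H / within-cell E decomposition
#'
#' Decomposes the sums of squares and cross-products (SSCP) of a feature
#' dataset into a between-group effect matrix `H` and a residual matrix `E`.
#' `H` is the SSCP of the group mean vectors about the grand mean, each
#' subject x condition observation counted once; `E` is the residual SSCP
#' about the group x condition cell means, so fixed condition offsets never
#' enter either matrix.  Subjects' repeated conditions are treated as
#' independent observations: the F-ratio resampling is designed to absorb
#' the person-level dependence, so the repeated-measures covariance is
#' deliberately not modelled here.
#'
#' The multivariate test statistics are functions of the eigenvalues
#' `c_1 >= ... >= c_s >= 0` of `H E^-1`.  In the univariate case the single
#' eigenvalue is the classical ratio of treatment to error sum of squares,
#' `h^2 / e^2`.
#'
#' @param fd a [feature_dataset()] with at least two groups.
#' @param effect the tested factor; only `"group"` is supported.
#' @return an object of class `effect_decomposition`: a list with `H`, `E`
#'   (n x n matrices), `df_h = G - 1`, `df_e = N_obs - G * k`, `eigenvalues`
#'   (descending, clamped at 0), `vectors` (eigenvectors of `H E^-1`,
#'   columns matching `eigenvalues`), `s` (numerical rank of `H E^-1`),
#'   `diag_he` (diagonal of `H E^-1`), and `F_univ` (per-measure univariate
#'   F values `H_jj / E_jj * df_e / df_h`).
#' @export
manova_decompose <- function(fd, effect = "group") {
  validate_feature_dataset(fd)
  effect <- match.arg(effect, "group")
  grp <- factor(fd$group, levels = unique(fd$group))
  if (nlevels(grp) < 2L) {
    stop("need at least 2 groups to decompose a group effect", call. = FALSE)
  }
  dec <- sscp_core(fd$values, as.integer(grp))
  dimnames(dec$H) <- dimnames(dec$E) <- list(fd$measures, fd$measures)
  names(dec$F_univ) <- names(dec$diag_he) <- fd$measures
  dec$measures <- fd$measures
  class(dec) <- "effect_decomposition"
  dec
}

# Fast SSCP core on the raw array; values [S, k, n], gi integer group index.
sscp_core <- function(values, gi) {
  S <- dim(values)[1L]; k <- dim(values)[2L]; n <- dim(values)[3L]
  G <- max(gi)
  X <- matrix(values, nrow = S * k, ncol = n)   # row (s, t): s fastest
  g_obs <- rep.int(gi, k)
  cell <- rep.int(gi, k) + G * rep(seq_len(k) - 1L, each = S)
  N <- S * k

  grand <- colSums(X) / N

  gsum <- rowsum(X, g_obs, reorder = TRUE)
  ng <- tabulate(g_obs, nbins = G)
  gm <- gsum / ng
  gd <- sweep(gm, 2L, grand) * sqrt(ng)
  H <- crossprod(gd)

  csum <- rowsum(X, cell, reorder = TRUE)
  nc <- tabulate(cell, nbins = G * k)
  cm <- csum / nc
  E <- crossprod(X) - crossprod(cm * sqrt(nc))
  E <- (E + t(E)) / 2

  df_h <- G - 1L
  df_e <- N - G * k
  if (df_e < 1L) stop("no residual degrees of freedom", call. = FALSE)

  diag_h <- diag(H); diag_e <- diag(E)
  if (any(diag_e <= 0)) {
    stop("residual SSCP matrix is singular; use more observations or fewer ",
         "measures", call. = FALSE)
  }
  F_univ <- (diag_h / diag_e) * (df_e / df_h)

  # eigenvalues of H E^-1 via the symmetric form R^-T H R^-1, E = R'R
  R <- tryCatch(chol(E), error = function(e) NULL)
  if (is.null(R)) {
    stop("residual SSCP matrix is singular; use more observations or fewer ",
         "measures", call. = FALSE)
  }
  M <- backsolve(R, t(backsolve(R, t(H), transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  # eigenvectors of H E^-1 are R' w for eigenvectors w of M
  V <- crossprod(R, es$vectors)
  Einv <- chol2inv(R)
  diag_he <- rowSums(H * Einv)   # diag(H %*% Einv), Einv symmetric
  tol <- if (ev[1L] > 0) 1e-10 * ev[1L] else 1e-12
  s <- sum(ev > tol)
  list(H = H, E = E, df_h = df_h, df_e = df_e,
       eigenvalues = ev, vectors = V, s = s,
       diag_he = diag_he, F_univ = F_univ)
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("Effect decomposition (group): n =", length(x$measures),
      "measures, df_h =", x$df_h, ", df_e =", x$df_e, "\n")
  cat("  eigenvalues of H E^-1:",
      paste(signif(x$eigenvalues, 5), collapse = ", "),
      " (rank s =", x$s, ")\n")
  cat("  univariate F:",
      paste(sprintf("%s = %.4g", names(x$F_univ), x$F_univ),
            collapse = ", "), "\n")
  invisible(x)
}

#' Multivariate F statistics from an effect decomposition
#'
#' The three classical constructions from the eigenvalues `c_i` of
#' `H E^-1` (with `r = df_e / df_h`):
#' \describe{
#'   \item{hotelling}{Hotelling-Lawley trace, `F = (sum c_i / s) * r`}
#'   \item{pillai}{Pillai's trace, `F = P / (s - P) * r` with
#'     `P = sum c_i / (1 + c_i)`}
#'   \item{roy}{Roy's largest root, `F = c_1 * r`}
#' }
#' For `s = 1` the three coincide.  With a single measure each reduces to
#' the univariate ANOVA F, `(h^2 / e^2) * df_e / df_h`.
#'
#' @param dec an `effect_decomposition` from [manova_decompose()].
#' @param stattype one of `"hotelling"`, `"pillai"`, `"roy"`.
#' @return an object of class `manova_f`: list with `stattype`, `value`,
#'   `df_h`, `df_e`, `s`.
#' @export
manova_f <- function(dec, stattype = c("hotelling", "pillai", "roy")) {
  stattype <- match.arg(stattype)
  if (dec$s < 1L) {
    stop("degenerate effect: H E^-1 has rank 0 (no group effect variance)",
         call. = FALSE)
  }
  structure(list(stattype = stattype,
                 value = manova_f_value(dec$eigenvalues[seq_len(dec$s)],
                                        dec$s, dec$df_h, dec$df_e, stattype),
                 df_h = dec$df_h, df_e = dec$df_e, s = dec$s),
            class = "manova_f")
}

manova_f_value <- function(cv, s, df_h, df_e, stattype) {
  r <- df_e / df_h
  switch(stattype,
         hotelling = sum(cv) / s * r,
         pillai = {
           P <- sum(cv / (1 + cv))
           P / (s - P) * r
         },
         roy = cv[1L] * r)
}

#' @export
print.manova_f <- function(x, ...) {
  cat(sprintf("Multivariate F (%s): %.6g on (%d, %d) df, s = %d\n",
              x$stattype, x$value, x$df_h, x$df_e, x$s))
  invisible(x)
}

#' Attribute eigenvalues of H E^-1 to individual measures
#'
#' Produces a non-negative `s x n` matrix `k[i, j]` distributing each
#' df-adjusted eigenvalue `c_i * df_e / df_h` over the per-measure F values
#' `F_j` read off the diagonal of `H E^-1`, such that the reconstruction
#' identity `sum_j k[i, j] * F_j = c_i * df_e / df_h` holds exactly for
#' every `i`.  Each diagonal entry `d_j` of `H E^-1` is distributed over
#' the retained eigendirections proportionally to the squared eigenvector
#' loadings `(v_{i,j})^2` (normalized across directions), then each row is
#' rescaled so the identity is exact.  This collapses to a 0/1 selection
#' matrix when `H` and `E` are diagonal (uncorrelated measures) and, for a
#' rank-one effect (`s = 1`, e.g. two groups), reduces to `k[1, j] = 1`
#' for every measure — the trace picture: the diagonal of `H E^-1`
#' represents, on average, the individual F values, and the single
#' df-adjusted eigenvalue is their sum.  Keeping the trace picture exact
#' at `s = 1` is what makes the normalized statistic `teststat1R` center
#' at 1 under the null; attributions that re-use the full-sample loadings
#' as relative weights instead inflate it, because the loadings are
#' selected by the very noise the resampling measures.
#'
#' @param dec an `effect_decomposition` from [manova_decompose()].
#' @return a matrix `k` with `dec$s` rows and one column per measure;
#'   attribute `"F_diag"` carries the diagonal-based per-measure F values
#'   used in the identity.
#' @export
eigen_contributions <- function(dec) {
  s <- dec$s
  if (s < 1L) stop("degenerate effect: rank 0", call. = FALSE)
  n <- length(dec$measures)
  r <- dec$df_e / dec$df_h
  F_diag <- dec$diag_he * r
  cv <- dec$eigenvalues[seq_len(s)]
  V <- dec$vectors[, seq_len(s), drop = FALSE]
  d <- pmax(dec$diag_he, 0)
  # share of diagonal entry d_j attributed to direction i: squared
  # loading, normalized across the retained directions
  U <- t(V^2)                                           # s x n
  colsum <- colSums(U)
  U <- sweep(U, 2L, ifelse(colsum > 0, colsum, 1), `/`)
  K <- matrix(0, nrow = s, ncol = n,
              dimnames = list(NULL, dec$measures))
  for (i in seq_len(s)) {
    ci_tilde <- sum(U[i, ] * d)
    if (ci_tilde <= 0 || all(F_diag[U[i, ] > 0] == 0)) {
      # no usable diagonal signal: attribute uniformly over measures
      message("eigen_contributions: zero diagonal contribution for ",
              "eigenvalue ", i, "; falling back to uniform attribution")
      ki <- rep(1 / n, n) * cv[i] * r / F_diag
      ki[!is.finite(ki)] <- 0
    } else {
      ki <- (cv[i] / ci_tilde) * U[i, ] * d / F_diag
      ki[!is.finite(ki)] <- 0
    }
    # rescale so the reconstruction identity is exact
    tot <- sum(ki * F_diag)
    if (tot > 0) ki <- ki * (cv[i] * r / tot)
    K[i, ] <- ki
  }
  attr(K, "F_diag") <- F_diag
  K
}

#' Method-of-moments variance components for one measure
#'
#' On the subject x condition table of a single measure, after removing
#' condition means, estimates the error variance `sigma_e^2` (residual mean
#' square of the two-way subject + condition layout) and the person-effect
#' variance `sigma_p^2 = max(0, (MS_subject - MS_residual) / k)`.  A
#' negative subtractive estimate is clamped to zero, the standard
#' method-of-moments convention.
#'
#' When a fixed group effect is present it inflates the subject mean square
#' and hence `sigma_p^2`; under the no-group-effect null the estimates
#' target the generative variances of [simulate_dataset()].
#'
#' @param fd a [feature_dataset()] with at least 2 conditions.
#' @param measure measure name (default: the first measure).
#' @return a list of class `variance_components` with `sigma_e2`,
#'   `sigma_p2`, `ms_subject`, `ms_residual`, `k`.
#' @export
estimate_variance_components <- function(fd, measure = fd$measures[1L]) {
  validate_feature_dataset(fd)
  k <- length(fd$conditions)
  if (k < 2L) {
    stop("variance components not separable with a single condition",
         call. = FALSE)
  }
  measure <- match.arg(measure, fd$measures)
  Y <- fd$values[, , measure, drop = TRUE]          # S x k
  S <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))                   # remove condition means
  sm <- rowMeans(Yc)
  ms_subject <- k * sum((sm - mean(sm))^2) / (S - 1L)
  resid <- sweep(Yc, 1L, sm)
  ms_residual <- sum(resid^2) / ((S - 1L) * (k - 1L))
  structure(list(sigma_e2 = ms_residual,
                 sigma_p2 = max(0, (ms_subject - ms_residual) / k),
                 ms_subject = ms_subject, ms_residual = ms_residual, k = k),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components: sigma_e^2 = %.5g, sigma_p^2 = %.5g\n",
              x$sigma_e2, x$sigma_p2))
  invisible(x)
}

#' Classical mixed-model group test for one measure
#'
#' The classical way of guarding a group test against the sample-specific
#' (random) subject effect: the error term is enhanced from the residual to
#' the subject-within-group mean square, `F = MS_group / MS_subject(group)`
#' on `(G - 1, N_subjects - G)` degrees of freedom.  On a balanced design
#' this is the one-way ANOVA of the per-subject means.
#'
#' @param fd a [feature_dataset()] with >= 2 groups, each with >= 2
#'   subjects.
#' @param measure measure name (default: the first measure).
#' @return a list of class `classical_mixed_f` with `statistic`, `df1`,
#'   `df2`, `p.value` (upper tail of the F distribution), `ms_group`,
#'   `ms_subject`.
#' @export
classical_mixed_f <- function(fd, measure = fd$measures[1L]) {
  validate_feature_dataset(fd)
  measure <- match.arg(measure, fd$measures)
  grp <- factor(fd$group, levels = unique(fd$group))
  G <- nlevels(grp)
  if (G < 2L) stop("need at least 2 groups", call. = FALSE)
  tab <- table(grp)
  if (any(tab < 2L)) {
    stop("each group needs at least 2 subjects for the subject-within-group ",
         "error term", call. = FALSE)
  }
  k <- length(fd$conditions)
  Y <- matrix(fd$values[, , measure], nrow = length(fd$subjects))
  sm <- rowMeans(Y)                                    # per-subject means
  N <- length(sm)
  gm <- tapply(sm, grp, mean)
  grand <- mean(sm)
  ms_group <- k * sum(as.integer(tab) * (gm - grand)^2) / (G - 1L)
  ms_subject <- k * sum((sm - gm[grp])^2) / (N - G)
  Fv <- ms_group / ms_subject
  structure(list(statistic = Fv, df1 = G - 1L, df2 = N - G,
                 p.value = stats::pf(Fv, G - 1L, N - G, lower.tail = FALSE),
                 ms_group = ms_group, ms_subject = ms_subject),
            class = "classical_mixed_f")
}

#' @export
print.classical_mixed_f <- function(x, ...) {
  cat(sprintf("Classical mixed-model F: %.5g on (%d, %d) df, p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}
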