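#' Two-class Fisher discriminant with fractional feature weights
#'
#' Projects the subjects of one condition onto the main discriminant axis
#' after standardizing each retained measure (zero mean, unit s.d. across
#' all subjects) and multiplying it by its fractional weight, so a weight
#' acts on comparable scales.  Zero-weight measures are excluded before
#' the axis is computed and therefore cannot perturb the scores.  The axis
#' is the classical Fisher direction `w = S_pooled^-1 (m_2 - m_1)`
#' (essentially a rotation of the coordinate system); subjects are
#' classified to the nearest group mean on the axis.
#'
#' @param fd a [feature_dataset()] with exactly 2 groups.
#' @param weights a [build_feature_weights()] result, or a named numeric
#'   vector of weights in `[0, 1]`.
#' @param condition condition label to analyze (default: the first).
#' @param method `"resubstitution"` (default) or `"loo"`
#'   (leave-one-out: axis and group means refit without the held-out
#'   subject).
#' @return an object of class `discriminant_result`: list with
#'   `axis_scores` (named per-subject projections), `predicted`,
#'   `actual`, `accuracy`, `group_means` (on the axis), `axis`
#'   (the weighted-space direction), `measures` (retained measures),
#'   `weights`, `condition`, `method`.
#' @export
weighted_discriminant <- function(fd, weights,
                                  condition = fd$conditions[1L],
                                  method = c("resubstitution", "loo")) {
  validate_feature_dataset(fd)
  method <- match.arg(method)
  if (inherits(weights, "weighted_feature_vector")) {
    weights <- weights$weights
  }
  if (is.null(names(weights))) {
    stop("weights must be named by measure", call. = FALSE)
  }
  condition <- match.arg(condition, fd$conditions)
  grp <- factor(fd$group, levels = unique(fd$group))
  if (nlevels(grp) != 2L) {
    stop("the weighted discriminant handles exactly 2 groups",
         call. = FALSE)
  }
  keep <- names(weights)[weights > 0]
  unknown <- setdiff(keep, fd$measures)
  if (length(unknown)) {
    stop("unknown measure(s) in weights: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 1L) {
    stop("no measure has positive weight", call. = FALSE)
  }

  X <- fd$values[, condition, keep, drop = FALSE]
  X <- matrix(X, nrow = length(fd$subjects), ncol = length(keep),
              dimnames = list(fd$subjects, keep))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("measure(s) constant across subjects: ",
         paste(keep[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)                                    # standardize
  W <- sweep(Z, 2L, weights[keep], `*`)            # then weight

  fit_axis <- function(Wtr, gtr) {
    m1 <- colMeans(Wtr[gtr == levels(grp)[1L], , drop = FALSE])
    m2 <- colMeans(Wtr[gtr == levels(grp)[2L], , drop = FALSE])
    S1 <- crossprod(sweep(Wtr[gtr == levels(grp)[1L], , drop = FALSE],
                          2L, m1))
    S2 <- crossprod(sweep(Wtr[gtr == levels(grp)[2L], , drop = FALSE],
                          2L, m2))
    Sp <- (S1 + S2) / (nrow(Wtr) - 2L)
    w <- tryCatch(solve(Sp, m2 - m1), error = function(e)
      stop("singular pooled covariance; use fewer measures",
           call. = FALSE))
    list(w = w, mu1 = sum(w * m1), mu2 = sum(w * m2))
  }

  if (method == "resubstitution") {
    ax <- fit_axis(W, grp)
    scores <- drop(W %*% ax$w)
    predicted <- ifelse(abs(scores - ax$mu1) <= abs(scores - ax$mu2),
                        levels(grp)[1L], levels(grp)[2L])
    group_means <- c(ax$mu1, ax$mu2)
    axis <- ax$w
  } else {
    n_sub <- nrow(W)
    scores <- numeric(n_sub)
    predicted <- character(n_sub)
    for (i in seq_len(n_sub)) {
      ax <- fit_axis(W[-i, , drop = FALSE], grp[-i])
      scores[i] <- sum(W[i, ] * ax$w)
      predicted[i] <- ifelse(abs(scores[i] - ax$mu1) <=
                               abs(scores[i] - ax$mu2),
                             levels(grp)[1L], levels(grp)[2L])
    }
    ax <- fit_axis(W, grp)
    group_means <- c(ax$mu1, ax$mu2)
    axis <- ax$w
  }
  names(scores) <- fd$subjects
  names(group_means) <- levels(grp)
  structure(list(axis_scores = scores, predicted = predicted,
                 actual = as.character(grp),
                 accuracy = mean(predicted == as.character(grp)),
                 group_means = group_means, axis = axis,
                 measures = keep, weights = weights[keep],
                 condition = condition, method = method),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf(
    "Weighted Fisher discriminant (condition %s, %s accuracy)\n",
    x$condition, x$method))
  cat("  measures: ",
      paste(sprintf("%s (w = %.2f)", x$measures, x$weights),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  group means on axis: %s = %.4g, %s = %.4g\n",
              names(x$group_means)[1L], x$group_means[1L],
              names(x$group_means)[2L], x$group_means[2L]))
  cat(sprintf("  correct classification: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}
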