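#' Hypothesis specification for Bayesian weighting
#'
#' A candidate hypothesis "this collection of measures displays a group
#' difference", characterized by the significance probability `pi` at which
#' the F-ratio test flagged it: `pi = P[B | H0]`, the chance of an outcome
#' at least as extreme under the null.  `prior_c` is the a priori
#' probability of the null (no preference: 0.5) and `c2 = P[B | H1]` is
#' assumed common across alternatives (no preference for any alternative),
#' in which case it cancels from all relative weights.
#'
#' @param features character vector of measure names spanned by the
#'   alternative.
#' @param pi significance probability in (0, 1).
#' @param prior_c a priori `P[H0]` in (0, 1); default 0.5.
#' @param c2 `P[B | H1]` in (0, 1]; default 1.
#' @return a list of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(features, pi, prior_c = 0.5, c2 = 1) {
  features <- as.character(features)
  if (length(features) < 1L || anyDuplicated(features)) {
    stop("features must be a non-empty set of distinct measure names",
         call. = FALSE)
  }
  if (!(pi > 0 && pi < 1)) stop("pi must lie in (0, 1)", call. = FALSE)
  if (!(prior_c > 0 && prior_c < 1)) {
    stop("prior_c must lie in (0, 1)", call. = FALSE)
  }
  if (!(c2 > 0 && c2 <= 1)) stop("c2 must lie in (0, 1]", call. = FALSE)
  structure(list(features = features, pi = pi, prior_c = prior_c, c2 = c2),
            class = "hypothesis_spec")
}

#' Posterior probabilities of the null and the alternative
#'
#' Bayes' rule applied to the significance outcome `B`:
#' `P[H0 | B] = c pi / (c pi + c2 (1 - c))` and its complement, with
#' `c = prior_c`.
#'
#' @param h a [hypothesis_spec()].
#' @return named numeric vector `c(H0 = ..., H1 = ...)` summing to 1.
#' @export
posterior_probs <- function(h) {
  stopifnot(inherits(h, "hypothesis_spec"))
  num0 <- h$prior_c * h$pi
  num1 <- h$c2 * (1 - h$prior_c)
  c(H0 = num0 / (num0 + num1), H1 = num1 / (num0 + num1))
}

#' Likelihood ratio of the alternative against the null
#'
#' `P[H1 | B] / P[H0 | B] = c2 (1 - c) / (c pi)`: the weight with which
#' the alternative is preferable when the null's weight is set to 1.
#'
#' @inheritParams posterior_probs
#' @return a positive scalar.
#' @export
likelihood_ratio <- function(h) {
  stopifnot(inherits(h, "hypothesis_spec"))
  h$c2 * (1 - h$prior_c) / (h$prior_c * h$pi)
}

#' Relative weight of a less significant alternative
#'
#' The ratio of the two alternatives' likelihood ratios against the null.
#' With the more significant (anchor) hypothesis at weight 1, the other
#' enters with weight `pi_anchor / pi_other` (uncorrected), which is < 1
#' since smaller `pi` means stronger evidence.  Because `P[B | H1] = c2`
#' is exact only for small `pi`, the default applies a finite-`pi`
#' correction consistent with posterior odds,
#' `pi_anchor (1 - pi_other) / (pi_other (1 - pi_anchor))`.
#'
#' For the canonical pair `(0.05, 0.10)` the corrected weight is 0.4737
#' (0.5 uncorrected).
#'
#' @param pi_anchor significance probability of the anchor (more
#'   significant) hypothesis.
#' @param pi_other significance probability of the other hypothesis;
#'   requires `pi_anchor <= pi_other`.
#' @param corrected apply the finite-`pi` correction (default `TRUE`).
#' @return a weight in (0, 1].
#' @export
relative_weight <- function(pi_anchor, pi_other, corrected = TRUE) {
  if (!(pi_anchor > 0 && pi_other < 1 && pi_anchor <= pi_other)) {
    stop("need 0 < pi_anchor <= pi_other < 1 (anchor is the more ",
         "significant hypothesis)", call. = FALSE)
  }
  w <- pi_anchor / pi_other
  if (corrected) w <- w * (1 - pi_other) / (1 - pi_anchor)
  w
}

#' Build fractional feature weights from nested hypotheses
#'
#' Takes an ordered list of nested hypotheses (each later feature set
#' extends an earlier one, with non-decreasing `pi`): the features of the
#' most significant hypothesis anchor the vector at weight 1; each feature
#' first appearing in a later hypothesis enters with
#' [relative_weight()]`(pi_anchor, pi_later)`.  Weights falling below
#' `drop_threshold` are set exactly to 0 and the measure is dropped,
#' reducing the feature-vector dimension.
#'
#' @param hypotheses list of [hypothesis_spec()] objects sorted by `pi`
#'   ascending with nested feature sets.  Exact duplicates are ignored,
#'   so re-listing the same hypotheses leaves the result unchanged.
#' @param drop_threshold weights below this value are zeroed
#'   (default 0.05).
#' @param corrected passed to [relative_weight()].
#' @return an object of class `weighted_feature_vector`: list with
#'   `weights` (named vector in `[0, 1]`, max exactly 1), `anchor`
#'   (features at weight 1 and the anchor `pi`), `dropped` (measures set
#'   to 0), `pis` (per-feature originating `pi`).
#' @export
build_feature_weights <- function(hypotheses, drop_threshold = 0.05,
                                  corrected = TRUE) {
  if (inherits(hypotheses, "hypothesis_spec")) hypotheses <-
      list(hypotheses)
  stopifnot(length(hypotheses) >= 1L,
            all(vapply(hypotheses, inherits, logical(1L),
                       "hypothesis_spec")))
  sig <- vapply(hypotheses, function(h)
    paste(h$pi, paste(sort(h$features), collapse = ","), sep = "|"),
    character(1L))
  hypotheses <- hypotheses[!duplicated(sig)]
  pis <- vapply(hypotheses, `[[`, numeric(1L), "pi")
  if (is.unsorted(pis)) {
    stop("hypotheses must be sorted by pi ascending (most significant ",
         "first)", call. = FALSE)
  }
  feats <- lapply(hypotheses, `[[`, "features")
  for (l in seq_along(feats)[-1L]) {
    if (!all(feats[[l - 1L]] %in% feats[[l]])) {
      stop("non-nested hypotheses: each feature set must extend the ",
           "previous one", call. = FALSE)
    }
  }
  anchor_pi <- pis[1L]
  weights <- stats::setNames(rep(1, length(feats[[1L]])), feats[[1L]])
  feat_pi <- stats::setNames(rep(anchor_pi, length(feats[[1L]])),
                             feats[[1L]])
  for (l in seq_along(feats)[-1L]) {
    new_feats <- setdiff(feats[[l]], names(weights))
    if (length(new_feats) == 0L) next
    w <- relative_weight(anchor_pi, pis[l], corrected = corrected)
    weights[new_feats] <- w
    feat_pi[new_feats] <- pis[l]
  }
  dropped <- names(weights)[weights < drop_threshold]
  weights[dropped] <- 0
  structure(list(weights = weights,
                 anchor = list(features = feats[[1L]], pi = anchor_pi),
                 dropped = dropped, pis = feat_pi,
                 drop_threshold = drop_threshold, corrected = corrected),
            class = "weighted_feature_vector")
}

#' @export
print.weighted_feature_vector <- function(x, ...) {
  cat("Weighted feature vector (anchor pi =", x$anchor$pi, ")\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-12s %.2f%s\n", nm, x$weights[nm],
                if (nm %in% x$dropped) "  (dropped)" else ""))
  }
  invisible(x)
}

#' Serialize a weighted feature vector to JSON
#' @param x a `weighted_feature_vector`.
#' @param path optional output path.
#' @return JSON string, invisibly when written to file.
#' @export
weights_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "weighted_feature_vector"))
  js <- jsonlite::toJSON(
    list(weights = as.list(x$weights), anchor = x$anchor,
         dropped = x$dropped, pis = as.list(x$pis),
         drop_threshold = x$drop_threshold, corrected = x$corrected),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
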