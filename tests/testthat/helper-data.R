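# Fixture builders shared across the suite; everything is generated in code.

# Small long-format data.frame: 2 groups x n_per x k conditions x measures.
make_long_df <- function(n_per = 3, k = 2, measures = c("x"), seed = 1,
                         shift = 0) {
  set.seed(seed)
  subj <- paste0("s", seq_len(2 * n_per))
  df <- expand.grid(subject = subj, condition = paste0("c", seq_len(k)),
                    stringsAsFactors = FALSE)
  df$group <- ifelse(match(df$subject, subj) <= n_per, "g1", "g2")
  for (m in measures) {
    df[[m]] <- rnorm(nrow(df)) + shift * (df$group == "g2")
  }
  df[, c("subject", "group", "condition", measures)]
}

make_fd <- function(...) feature_dataset(make_long_df(...))

# Independent brute-force SSCP oracle: direct loops over observations.
brute_sscp <- function(fd) {
  df <- as.data.frame(fd)
  meas <- fd$measures
  X <- as.matrix(df[, meas, drop = FALSE])
  n <- length(meas)
  grand <- colMeans(X)
  H <- matrix(0, n, n)
  for (g in unique(df$group)) {
    rows <- df$group == g
    d <- colMeans(X[rows, , drop = FALSE]) - grand
    H <- H + sum(rows) * outer(d, d)
  }
  E <- matrix(0, n, n)
  for (g in unique(df$group)) {
    for (cc in unique(df$condition)) {
      rows <- df$group == g & df$condition == cc
      cm <- colMeans(X[rows, , drop = FALSE])
      for (i in which(rows)) {
        d <- X[i, ] - cm
        E <- E + outer(d, d)
      }
    }
  }
  G <- length(unique(df$group)); k <- length(unique(df$condition))
  list(H = H, E = E, df_h = G - 1, df_e = nrow(df) - G * k)
}

# Forge a minimal resample_summary-like object from per-measure F draws.
forge_rs <- function(f_matrix, f_multi, full = NULL,
                     stattype = "hotelling") {
  pm <- lapply(seq_len(ncol(f_matrix)), function(j)
    fratiotest:::summarize_f(f_matrix[, j]))
  names(pm) <- colnames(f_matrix)
  out <- c(fratiotest:::summarize_f(f_multi),
           list(m = nrow(f_matrix), p = 2 / 3, stattype = stattype,
                seed = NA_integer_, per_measure = pm, f_matrix = f_matrix,
                full = full, df_k = 1, df_ek = 28, df_e_sub = 16))
  class(out) <- "resample_summary"
  out
}

# Forge an effect_decomposition with given H, E (diagonal tests etc.).
forge_dec <- function(H, E, df_h, df_e) {
  n <- nrow(H)
  Einv <- solve(E)
  HE <- H %*% Einv
  es <- eigen(Einv %*% H)   # same eigenvalues as H E^-1
  ev <- pmax(Re(es$values), 0)
  ord <- order(ev, decreasing = TRUE)
  ev <- ev[ord]
  V <- Re(eigen(HE)$vectors)[, order(Re(eigen(HE)$values),
                                     decreasing = TRUE), drop = FALSE]
  tol <- if (ev[1] > 0) 1e-10 * ev[1] else 1e-12
  structure(list(H = H, E = E, df_h = df_h, df_e = df_e,
                 eigenvalues = ev, vectors = V, s = sum(ev > tol),
                 diag_he = diag(HE),
                 F_univ = diag(H) / diag(E) * (df_e / df_h),
                 measures = colnames(H) %||% paste0("v", seq_len(n))),
            class = "effect_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
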