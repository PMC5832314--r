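#' Source classification rate of a tracer set
#'
#' Fits a linear discriminant function on the named tracers and returns the
#' percentage of source samples assigned to their true category. By default
#' this is resubstitution (training-set) accuracy — the "% classified
#' correctly" a stepwise DFA reports; set `cv = TRUE` for leave-one-out
#' cross-validation instead.
#'
#' A singular within-group covariance (constant or collinear tracers) makes
#' `MASS::lda` refuse the fit; in that case a ridge-regularized pooled
#' covariance discriminant is used and a warning is raised.
#'
#' @param sources `sample_table` of source samples; >= 2 categories with
#'   >= 2 samples each.
#' @param tracers character vector of tracer names to classify on.
#' @param cv logical; leave-one-out instead of resubstitution.
#' @return classification percentage in \[0, 100\].
#' @export
classify_rate <- function(sources, tracers, cv = FALSE) {
  if (length(tracers) == 0L) stop("classify_rate: empty tracer set", call. = FALSE)
  X <- as.matrix(sources[, tracers, drop = FALSE])
  g <- factor(sources$category)
  if (nlevels(g) < 2L) stop("classify_rate: need >= 2 categories", call. = FALSE)
  if (any(table(g) < 2L)) stop("classify_rate: each category needs >= 2 samples", call. = FALSE)
  fit <- tryCatch(
    suppressWarnings(MASS::lda(X, grouping = g, CV = cv)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    pred <- if (cv) fit$class else stats::predict(fit, X)$class
    return(100 * mean(pred == g))
  }
  warning("classify_rate: singular within-group covariance; ",
          "using ridge-regularized discriminant", call. = FALSE)
  100 * mean(ridge_lda_predict(X, g, cv = cv) == g)
}

# Linear discriminant scores from a ridge-regularized pooled covariance,
# used only when the within-group covariance is singular.
ridge_lda_predict <- function(X, g, cv = FALSE) {
  classify <- function(Xtr, gtr, Xte) {
    lev <- levels(gtr)
    mu <- t(vapply(lev, function(l) colMeans(Xtr[gtr == l, , drop = FALSE]),
                   numeric(ncol(Xtr))))
    centered <- Xtr - mu[as.integer(gtr), , drop = FALSE]
    S <- crossprod(centered) / max(1, nrow(Xtr) - length(lev))
    lambda <- 1e-8 * mean(diag(S)) + 1e-12
    Sinv <- solve(S + diag(lambda, ncol(Xtr)))
    prior <- as.numeric(table(gtr)) / length(gtr)
    scores <- vapply(seq_along(lev), function(k) {
      Xte %*% (Sinv %*% mu[k, ]) - 0.5 * drop(mu[k, ] %*% Sinv %*% mu[k, ]) +
        log(prior[k])
    }, numeric(nrow(Xte)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(Xte))
    factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  }
  if (!cv) return(classify(X, g, X))
  out <- g
  for (i in seq_len(nrow(X))) {
    out[i] <- classify(X[-i, , drop = FALSE], g[-i], X[i, , drop = FALSE])
  }
  out
}

#' Wilks' lambda of a tracer subset
#'
#' det(W)/det(T): the ratio of the within-group to the total sum-of-squares
#' generalized variance. Smaller is better separation; it is the fitness the
#' genetic algorithm minimizes. Near-singular matrices are ridged.
#'
#' @param sources `sample_table` of source samples.
#' @param tracers tracer names.
#' @return Wilks' lambda in (0, 1\].
#' @export
wilks_lambda <- function(sources, tracers) {
  X <- as.matrix(sources[, tracers, drop = FALSE])
  g <- factor(sources$category)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  centered <- X
  for (l in levels(g)) {
    idx <- g == l
    centered[idx, ] <- scale(X[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  Wm <- crossprod(centered)
  ridge <- 1e-10 * mean(diag(Tm)) + 1e-300
  p <- ncol(X)
  dW <- det(Wm + diag(ridge, p))
  dT <- det(Tm + diag(ridge, p))
  if (dT <= 0) return(1)
  min(1, max(dW / dT, .Machine$double.xmin))
}

# Stepwise F-to-enter for tracer j joining subset 'within' (which excludes j):
# F = ((1 - L)/L) * (n - g - p) / (g - 1), L = Lambda(S+j)/Lambda(S),
# p = |S|. Returns list(F, p_value); p_value NA when df exhausted.
f_to_enter <- function(sources, within, j) {
  n <- nrow(sources)
  g <- length(unique(sources$category))
  p <- length(within)
  l_full <- wilks_lambda(sources, c(within, j))
  l_red <- if (p == 0L) 1 else wilks_lambda(sources, within)
  L <- min(1, l_full / l_red)
  df2 <- n - g - p
  if (df2 < 1L) return(list(F = NA_real_, p_value = NA_real_))
  Fv <- ((1 - L) / max(L, .Machine$double.xmin)) * df2 / (g - 1)
  list(F = Fv, p_value = stats::pf(Fv, g - 1, df2, lower.tail = FALSE))
}

# TRUE when every tracer of the subset satisfies the stepwise-entry F test
# at p <= p_entry, taking each in turn as the last variable entered.
subset_entry_valid <- function(sources, tracers, p_entry) {
  for (j in tracers) {
    pv <- f_to_enter(sources, setdiff(tracers, j), j)$p_value
    if (is.na(pv) || pv > p_entry) return(FALSE)
  }
  TRUE
}
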