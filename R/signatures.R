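#' Tracer discriminatory weightings
#'
#' W_i = the ratio of each tracer's source-classification percentage to that
#' of the weakest tracer in the signature, so the weakest tracer gets
#' exactly 1.00 and every other weight is >= 1. Reported rounded to two
#' decimals, as in the mass-balance weighting tables.
#'
#' @param classification_pcts numeric vector of percentages in (0, 100].
#' @return numeric vector of weights, same order, rounded to 2 decimals.
#' @export
tdw <- function(classification_pcts) {
  p <- as.numeric(classification_pcts)
  if (length(p) == 0L) stop("tdw: empty percentage list", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 100)) {
    stop("tdw: percentages must lie in (0, 100]", call. = FALSE)
  }
  round(p / min(p), 2)
}

#' Construct a composite signature
#'
#' Bundles a selected tracer subset with its per-tracer classification
#' percentages, the discriminatory weightings derived from them, and the
#' overall classification percentage of the joint discriminant fit.
#'
#' @param method one of `"GA-DFA"`, `"KW-H"`, `"PCA"`.
#' @param tracers ordered tracer names.
#' @param sources `sample_table` used to compute classification rates.
#' @param cv logical, passed to [classify_rate()].
#' @return a `composite_signature` list with elements `method`, `tracers`,
#'   `classification_pct` (per tracer), `tdw`, `overall_pct`, `wilks`.
#' @export
composite_signature <- function(method, tracers, sources, cv = FALSE) {
  method <- match.arg(method, c("GA-DFA", "KW-H", "PCA"))
  per <- vapply(tracers, function(tc) classify_rate(sources, tc, cv = cv),
                numeric(1))
  structure(list(method = method,
                 tracers = tracers,
                 classification_pct = per,
                 tdw = stats::setNames(tdw(per), tracers),
                 overall_pct = classify_rate(sources, tracers, cv = cv),
                 wilks = wilks_lambda(sources, tracers)),
            class = "composite_signature")
}

#' @export
print.composite_signature <- function(x, ...) {
  cat("<composite_signature> ", x$method, ": ",
      paste(x$tracers, collapse = ", "),
      sprintf(" (overall %.0f%%)\n", x$overall_pct), sep = "")
  invisible(x)
}

#' Genetic-algorithm driven discriminant signature selection
#'
#' Searches tracer subsets with a genetic algorithm whose fitness is the
#' Wilks' lambda of the linear discriminant fit, subject to every member
#' tracer passing the stepwise-entry F test at `p_entry`. The search is
#' restarted `n_repeats` times and up to three distinct top signatures are
#' returned, ranked by overall classification percentage (descending) then
#' lambda (ascending); ties prefer the smaller subset, then lexicographic
#' tracer order.
#'
#' GA settings (population 50, 40 generations, uniform crossover 0.7,
#' per-bit mutation 0.02, elitism 2) are deliberately modest: the candidate
#' panels are small and fitness evaluations are cached across restarts.
#'
#' @param sources `sample_table` of source samples.
#' @param candidate_tracers tracers that passed the bracket test.
#' @param n_repeats number of GA restarts (default 200).
#' @param p_entry stepwise entry probability threshold (default 0.05).
#' @param seed integer seed for the GA's randomness.
#' @param n_signatures how many distinct top signatures to return (<= 3).
#' @param pop,generations,p_crossover,p_mutation,elitism GA hyperparameters.
#' @return list of up to `n_signatures` [composite_signature()] objects.
#' @export
select_ga_dfa <- function(sources, candidate_tracers, n_repeats = 200,
                          p_entry = 0.05, seed = 1L, n_signatures = 3L,
                          pop = 50L, generations = 40L, p_crossover = 0.7,
                          p_mutation = 0.02, elitism = 2L) {
  stopifnot(n_repeats >= 1)
  K <- length(candidate_tracers)
  if (K == 0L) stop("select_ga_dfa: no candidate tracers", call. = FALSE)
  if (K == 1L) {
    sig <- composite_signature("GA-DFA", candidate_tracers, sources)
    return(list(sig))
  }
  cache <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    idx <- which(bits == 1L)
    if (length(idx) == 0L) return(Inf)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    trs <- candidate_tracers[idx]
    val <- if (!subset_entry_valid(sources, trs, p_entry)) Inf else
      wilks_lambda(sources, trs)
    cache[[key]] <- val
    val
  }
  set.seed(as.integer(seed))
  for (rep_i in seq_len(n_repeats)) {
    P <- matrix(stats::rbinom(pop * K, 1L, 0.3), nrow = pop)
    P[rowSums(P) == 0L, sample.int(K, 1L)] <- 1L
    fit <- apply(P, 1, fitness)
    for (gen in seq_len(generations)) {
      ord <- order(fit)
      elite <- P[ord[seq_len(elitism)], , drop = FALSE]
      # binary tournament selection
      pick <- function() {
        ij <- sample.int(pop, 2L)
        ij[which.min(fit[ij])]
      }
      children <- matrix(0L, nrow = pop, ncol = K)
      for (c2 in seq(1, pop, by = 2)) {
        a <- P[pick(), ]; b <- P[pick(), ]
        if (stats::runif(1) < p_crossover) {
          mask <- stats::runif(K) < 0.5
          tmp <- a[mask]; a[mask] <- b[mask]; b[mask] <- tmp
        }
        children[c2, ] <- a
        if (c2 + 1 <= pop) children[c2 + 1, ] <- b
      }
      flip <- matrix(stats::runif(pop * K) < p_mutation, nrow = pop)
      children[flip] <- 1L - children[flip]
      children[rowSums(children) == 0L, sample.int(K, 1L)] <- 1L
      children[seq_len(elitism), ] <- elite
      P <- children
      fit <- apply(P, 1, fitness)
    }
  }
  # rank all feasible subsets ever evaluated
  keys <- ls(cache)
  vals <- vapply(keys, function(k) cache[[k]], numeric(1))
  keys <- keys[is.finite(vals)]
  if (length(keys) == 0L) {
    stop("select_ga_dfa: no tracer subset satisfies the stepwise entry test; ",
         "candidates may be degenerate: ",
         paste(candidate_tracers, collapse = ", "), call. = FALSE)
  }
  subsets <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1]]))
  lambda <- vapply(keys, function(k) cache[[k]], numeric(1))
  overall <- vapply(subsets, function(idx) {
    classify_rate(sources, candidate_tracers[idx])
  }, numeric(1))
  sizes <- lengths(subsets)
  lex <- vapply(subsets, function(idx) {
    paste(candidate_tracers[idx], collapse = "\001")
  }, character(1))
  ord <- order(-overall, lambda, sizes, lex)
  picked <- utils::head(ord, n_signatures)
  lapply(picked, function(i) {
    composite_signature("GA-DFA", candidate_tracers[subsets[[i]]], sources)
  })
}

#' Kruskal-Wallis signature selection
#'
#' Ranks candidate tracers by the Kruskal-Wallis H statistic across the
#' source categories, keeps those significant at `alpha`, and grows the
#' signature from the top of the ranking — starting at `min_size` tracers
#' and adding the next-ranked tracer while the discriminant classification
#' percentage keeps increasing (first non-improvement stops the growth).
#'
#' @param sources `sample_table` of source samples (>= 2 categories).
#' @param candidate_tracers tracers that passed the bracket test.
#' @param alpha significance threshold for the H test (default 0.05).
#' @param min_size minimum signature size (default 3, capped at the number
#'   of significant tracers).
#' @return a [composite_signature()] with method `"KW-H"`.
#' @export
select_kw_h <- function(sources, candidate_tracers, alpha = 0.05,
                        min_size = 3L) {
  g <- factor(sources$category)
  if (nlevels(g) < 2L) stop("select_kw_h: need >= 2 categories", call. = FALSE)
  kw <- t(vapply(candidate_tracers, function(tc) {
    res <- stats::kruskal.test(sources[[tc]], g)
    c(H = unname(res$statistic), p = res$p.value)
  }, numeric(2)))
  sig_idx <- which(kw[, "p"] < alpha)
  if (length(sig_idx) == 0L) {
    stop("select_kw_h: no tracer significant at alpha = ", alpha, call. = FALSE)
  }
  ranked <- candidate_tracers[sig_idx][order(-kw[sig_idx, "H"])]
  chosen <- grow_signature(sources, ranked, min_size)
  sig <- composite_signature("KW-H", chosen, sources)
  sig$kw_h <- stats::setNames(kw[, "H"], candidate_tracers)
  sig
}

#' PCA signature selection
#'
#' Principal components of the standardized source tracer matrix; tracers
#' are ranked by their maximum absolute loading across the first
#' `n_components` components (two components routinely explain nearly all
#' tracer variance in these panels) and the signature is grown as in
#' [select_kw_h()].
#'
#' @param sources `sample_table` (>= 3 samples).
#' @param candidate_tracers tracers that passed the bracket test.
#' @param n_components number of leading components (default 2).
#' @param min_size minimum signature size (default 3).
#' @return a [composite_signature()] with method `"PCA"`; the component
#'   loadings and explained-variance fractions ride along as `loadings`
#'   and `explained`.
#' @export
select_pca <- function(sources, candidate_tracers, n_components = 2L,
                       min_size = 3L) {
  if (nrow(sources) < 3L) stop("select_pca: need >= 3 samples", call. = FALSE)
  if (length(candidate_tracers) < n_components) {
    stop("select_pca: fewer tracers than components", call. = FALSE)
  }
  X <- as.matrix(sources[, candidate_tracers, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < n_components) {
    stop("select_pca: fewer varying tracers than components", call. = FALSE)
  }
  pca <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ncomp <- min(n_components, ncol(pca$rotation))
  load <- pca$rotation[, seq_len(ncomp), drop = FALSE]
  score <- apply(abs(load), 1, max)
  ranked <- names(sort(score, decreasing = TRUE))
  chosen <- grow_signature(sources, ranked, min_size)
  sig <- composite_signature("PCA", chosen, sources)
  sig$loadings <- load
  sig$explained <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(ncomp)]
  sig
}

# Grow a signature down a tracer ranking: start with min_size tracers, add
# the next while classification % strictly increases.
grow_signature <- function(sources, ranked, min_size) {
  min_size <- min(min_size, length(ranked))
  current <- ranked[seq_len(min_size)]
  best <- classify_rate(sources, current)
  for (i in seq(min_size + 1L, length.out = max(0L, length(ranked) - min_size))) {
    trial <- ranked[seq_len(i)]
    acc <- classify_rate(sources, trial)
    if (acc > best) {
      current <- trial
      best <- acc
    } else break
  }
  current
}
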