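#' Monte Carlo configuration
#'
#' @param n_accept number of viable (GOF-accepted) solutions to collect
#'   (default 5000).
#' @param gof_threshold acceptance threshold on the goodness of fit
#'   (default 0.85; a solution is viable when GOF > threshold).
#' @param n_bins number of equal-width bins over \[0, 1\] for the posterior
#'   relative-frequency distributions (default 100, i.e. 0.01 resolution).
#' @param max_draws cap on total mixing-model iterations (default
#'   100 * n_accept).
#' @param seed integer seed for the Latin hypercube draws.
#' @param batch draws generated per Latin hypercube block (default
#'   `n_accept`); stratification is within each block.
#' @return an `mc_config` list.
#' @export
mc_config <- function(n_accept = 5000L, gof_threshold = 0.85, n_bins = 100L,
                      max_draws = 100L * n_accept, seed = 1L,
                      batch = n_accept) {
  stopifnot(n_accept >= 1, gof_threshold >= 0, gof_threshold < 1, n_bins >= 2,
            max_draws >= n_accept, batch >= 1)
  structure(list(n_accept = as.integer(n_accept),
                 gof_threshold = gof_threshold,
                 n_bins = as.integer(n_bins),
                 max_draws = as.integer(max_draws),
                 seed = as.integer(seed),
                 batch = as.integer(batch)),
            class = "mc_config")
}

# Inverse-CDF truncated normal from uniform deviates; sigma = 0 collapses
# to the location, as does an empty truncation window.
truncnorm_from_uniform <- function(u, mu, sigma, lo, hi) {
  if (sigma <= 0) return(rep(mu, length(u)))
  plo <- stats::pnorm((lo - mu) / sigma)
  phi <- stats::pnorm((hi - mu) / sigma)
  if (phi - plo <= 0) return(rep(mu, length(u)))
  q <- stats::qnorm(plo + u * (phi - plo))
  pmin(pmax(mu + sigma * q, lo), hi)
}

#' Latin-hypercube deviate medians for one summary
#'
#' Draws `n_draws` deviate median values per tracer from
#' Normal(median, Qn) truncated to the tracer's observed \[min, max\],
#' stratified by Latin hypercube sampling: each tracer's probability axis is
#' split into `n_draws` equal strata, one draw falls in each stratum, and
#' the strata order is shuffled independently per tracer. A tracer with
#' Qn = 0 (or undefined Qn) yields a constant column at the median, with a
#' warning.
#'
#' @param summary a `group_summary` from [summarize_group()].
#' @param n_draws number of deviate rows.
#' @param seed integer seed.
#' @return `n_draws` x n_tracers matrix of deviate medians (columns named
#'   by tracer).
#' @export
sample_deviates <- function(summary, n_draws, seed = 1L) {
  set.seed(as.integer(seed))
  n_tr <- nrow(summary)
  u <- lhs::randomLHS(as.integer(n_draws), n_tr)
  qn <- summary$qn
  if (any(is.na(qn) | qn == 0)) {
    warning("sample_deviates: Qn = 0 (or undefined) for tracer(s) ",
            paste(summary$tracer[is.na(qn) | qn == 0], collapse = ", "),
            "; deviates are degenerate at the median", call. = FALSE)
  }
  out <- vapply(seq_len(n_tr), function(j) {
    truncnorm_from_uniform(u[, j], summary$median[j],
                           if (is.na(qn[j])) 0 else qn[j],
                           summary$min[j], summary$max[j])
  }, numeric(n_draws))
  if (is.null(dim(out))) out <- matrix(out, nrow = n_draws)
  colnames(out) <- summary$tracer
  out
}

#' Posterior distribution of accepted proportions for one source
#'
#' Bins the accepted Monte Carlo proportions into `n_bins` equal intervals
#' over \[0, 1\] and records the relative frequencies F_i, the bin midvalues
#' v_i, the relative frequency-weighted average median contribution
#' `R = sum_i v_i F_i`, and the full range of accepted values.
#'
#' @param accepted numeric vector of accepted proportions in \[0, 1\].
#' @param category source category label.
#' @param n_bins number of bins (default 100).
#' @return a `posterior_distribution`.
#' @export
posterior_distribution <- function(accepted, category = NA_character_,
                                   n_bins = 100L) {
  stopifnot(length(accepted) >= 1, all(accepted >= 0 & accepted <= 1))
  bin <- pmin(floor(accepted * n_bins) + 1L, n_bins)
  freq <- tabulate(bin, nbins = n_bins) / length(accepted)
  mid <- (seq_len(n_bins) - 0.5) / n_bins
  structure(list(category = category,
                 midvalues = mid,
                 frequencies = freq,
                 R = sum(mid * freq),
                 full_range = range(accepted),
                 n_accepted = length(accepted)),
            class = "posterior_distribution")
}

#' Frequency-weighted average median contribution
#'
#' `R = sum_i v_i F_i` over the posterior's bins. Errors if the frequencies
#' do not sum to 1.
#'
#' @param dist a [posterior_distribution()].
#' @return R in \[0, 1\].
#' @export
weighted_mean_R <- function(dist) {
  stopifnot(inherits(dist, "posterior_distribution"))
  if (abs(sum(dist$frequencies) - 1) > 1e-9) {
    stop("weighted_mean_R: frequencies are not normalized", call. = FALSE)
  }
  sum(dist$midvalues * dist$frequencies)
}

#' Qn-scaled Monte Carlo uncertainty analysis for one signature
#'
#' Repeatedly perturbs all source and sediment medians jointly — one Latin
#' hypercube row per iteration, each median drawn from Normal(median, Qn)
#' truncated to its observed range — solves the weighted mass-balance
#' problem, and accepts solutions whose goodness of fit exceeds the
#' threshold. Iterations continue until `n_accept` viable solutions are
#' found or `max_draws` is exhausted. Accepted proportions are binned into
#' posterior relative-frequency distributions per source category.
#'
#' @param signature a [composite_signature()].
#' @param source_summaries named list of `group_summary` objects, one per
#'   source category.
#' @param sediment_summary `group_summary` of the sediment samples.
#' @param cfg an [mc_config()].
#' @param literal_eq3 passed to the solver, see [mixing_objective()].
#' @param perturb_sediment logical; set FALSE to freeze the sediment
#'   medians and perturb the sources only.
#' @return an `mc_result` list: `posteriors` (named list of
#'   [posterior_distribution()]), `R` (named vector), `mean_gof`,
#'   `overall_pct`, `accepted` (matrix of accepted proportions), `gof`
#'   (accepted GOF values), `n_draws_used`, `signature`.
#' @export
run_monte_carlo <- function(signature, source_summaries, sediment_summary,
                            cfg = mc_config(), literal_eq3 = FALSE,
                            perturb_sediment = TRUE) {
  stopifnot(inherits(signature, "composite_signature"))
  tr <- signature$tracers
  categories <- names(source_summaries)
  m <- length(categories)
  for (ss in source_summaries) {
    if (!all(tr %in% ss$tracer)) {
      stop("run_monte_carlo: signature tracers missing from a source summary",
           call. = FALSE)
    }
  }
  if (!all(tr %in% sediment_summary$tracer)) {
    stop("run_monte_carlo: signature tracers missing from sediment summary",
         call. = FALSE)
  }
  n <- length(tr)
  pick <- function(summ) summ[match(tr, summ$tracer), , drop = FALSE]
  src <- lapply(source_summaries, pick)
  sed <- pick(sediment_summary)
  sv <- t(vapply(src, function(s) suppressWarnings(sv_weights(s)),
                 numeric(n)))
  w <- signature$tdw
  med_s <- t(vapply(src, function(s) s$median, numeric(n)))
  qn_s <- t(vapply(src, function(s) ifelse(is.na(s$qn), 0, s$qn), numeric(n)))
  lo_s <- t(vapply(src, function(s) s$min, numeric(n)))
  hi_s <- t(vapply(src, function(s) s$max, numeric(n)))
  qn_c <- ifelse(is.na(sed$qn), 0, sed$qn)
  if (!perturb_sediment) qn_c <- rep(0, n)

  set.seed(cfg$seed)
  accepted <- matrix(NA_real_, nrow = cfg$n_accept, ncol = m,
                     dimnames = list(NULL, categories))
  gofs <- numeric(cfg$n_accept)
  n_acc <- 0L
  n_drawn <- 0L
  best_gof <- -Inf
  dims <- (m + 1L) * n
  while (n_acc < cfg$n_accept && n_drawn < cfg$max_draws) {
    nb <- min(cfg$batch, cfg$max_draws - n_drawn)
    u <- lhs::randomLHS(nb, dims)
    for (r in seq_len(nb)) {
      ur <- u[r, ]
      s_dev <- med_s
      for (si in seq_len(m)) for (j in seq_len(n)) {
        s_dev[si, j] <- truncnorm_from_uniform(
          ur[(si - 1L) * n + j], med_s[si, j], qn_s[si, j],
          lo_s[si, j], hi_s[si, j])
      }
      c_dev <- vapply(seq_len(n), function(j) {
        truncnorm_from_uniform(ur[m * n + j], sed$median[j], qn_c[j],
                               sed$min[j], sed$max[j])
      }, numeric(1))
      n_drawn <- n_drawn + 1L
      if (any(c_dev == 0)) next
      prob <- mixing_problem(tr, categories, c_dev, s_dev, sv = sv, w = w)
      sol <- suppressWarnings(solve_mixing(prob, literal_eq3 = literal_eq3))
      best_gof <- max(best_gof, sol$gof)
      if (sol$gof > cfg$gof_threshold) {
        n_acc <- n_acc + 1L
        accepted[n_acc, ] <- sol$p
        gofs[n_acc] <- sol$gof
        if (n_acc >= cfg$n_accept) break
      }
    }
  }
  if (n_acc == 0L) {
    stop("run_monte_carlo: no viable solution within ", n_drawn,
         " draws; best GOF seen = ", signif(best_gof, 4), call. = FALSE)
  }
  accepted <- accepted[seq_len(n_acc), , drop = FALSE]
  gofs <- gofs[seq_len(n_acc)]
  posteriors <- lapply(categories, function(cat) {
    posterior_distribution(accepted[, cat], cat, cfg$n_bins)
  })
  names(posteriors) <- categories
  structure(list(posteriors = posteriors,
                 R = vapply(posteriors, function(d) d$R, numeric(1)),
                 mean_gof = mean(gofs),
                 overall_pct = signature$overall_pct,
                 accepted = accepted,
                 gof = gofs,
                 n_draws_used = n_drawn,
                 signature = signature),
            class = "mc_result")
}

#' Combine apportionments across composite signatures
#'
#' A subcatchment's final apportionment combines the per-signature
#' frequency-weighted contributions with a weight
#' `alpha_k = mean_gof_k * overall_classification_pct_k` — the product of
#' the goodness of fit and the discriminatory power each signature affords.
#' When any GOF is unavailable (`NA`/`NULL`), equal weights are used. The
#' combined proportions are reported rounded to 2 decimals.
#'
#' @param results list of per-signature results, each a list with elements
#'   `R` (named numeric per category), `mean_gof`, `overall_pct` — e.g.
#'   `mc_result` objects.
#' @return named numeric vector of combined proportions per category.
#' @export
combine_signatures <- function(results) {
  if (length(results) == 0L) stop("combine_signatures: empty input", call. = FALSE)
  categories <- names(results[[1]]$R)
  vals <- vapply(results, function(r) {
    if (!all(categories %in% names(r$R))) {
      stop("combine_signatures: category missing from a signature result",
           call. = FALSE)
    }
    r$R[categories]
  }, numeric(length(categories)))
  Rm <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
  alpha <- vapply(results, function(r) {
    g <- r$mean_gof
    pct <- r$overall_pct
    if (is.null(g) || is.na(g) || is.null(pct) || is.na(pct)) NA_real_
    else g * pct
  }, numeric(1))
  if (anyNA(alpha)) alpha <- rep(1, length(results))
  combined <- drop(alpha %*% Rm) / sum(alpha)
  round(stats::setNames(combined, categories), 2)
}

#' Catchment-wide average source contributions
#'
#' Unweighted arithmetic mean of the combined per-subcatchment proportions,
#' reported as percentages.
#'
#' @param per_subcatchment named list of combined proportion vectors (one
#'   per subcatchment, categories named identically).
#' @return named numeric vector of percentages per category.
#' @export
catchment_summary <- function(per_subcatchment) {
  stopifnot(length(per_subcatchment) >= 1)
  categories <- names(per_subcatchment[[1]])
  vals <- vapply(per_subcatchment, function(v) v[categories],
                 numeric(length(categories)))
  Rm <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1,
                                                 dimnames = list(NULL, categories))
  100 * colMeans(Rm)
}
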