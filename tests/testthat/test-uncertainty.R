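test_that("Qn equals the brute-force pairwise order statistic", {
  expect_equal(qn_scale(c(3, 3, 3, 3)), 0)
  expect_error(qn_scale(5), "at least 2")

  brute_qn <- function(x) {
    n <- length(x)
    d <- sort(as.vector(abs(outer(x, x, "-"))[lower.tri(diag(n))]))
    h <- floor(n / 2) + 1
    k <- choose(h, 2)
    small <- c(0.399, 0.994, 0.512, 0.844, 0.611, 0.857, 0.669, 0.872)
    cn <- if (n <= 9) small[n - 1] else if (n %% 2 == 1) n / (n + 1.4) else
      n / (n + 3.8)
    2.2219 * cn * d[k]
  }
  # the worked 4-point case: differences {1,2,3,4,6,7}, k = 3 -> 3
  x4 <- c(1, 2, 4, 8)
  expect_equal(brute_qn(x4), 2.2219 * 0.512 * 3)
  expect_equal(qn_scale(x4), brute_qn(x4))

  for (k in 1:8) {
    set.seed(600 + k)
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 5))
    expect_equal(qn_scale(x), brute_qn(x))
  }
})

test_that("Qn is a consistent scale estimate for the normal", {
  set.seed(12)
  x <- rnorm(10000)
  expect_equal(qn_scale(x), 1, tolerance = 0.05)
})

test_that("Latin hypercube deviates respect strata, bounds and moments", {
  panel <- small_panel(2)
  set.seed(2)
  vals <- cbind(rnorm(10, 10, 2), rep(4, 10))
  tab <- make_samples(vals, "source", "farmyard", panel = panel)
  summ <- suppressWarnings(summarize_group(tab))
  expect_warning(dev <- sample_deviates(summ, 64, seed = 4), "degenerate")

  # constant tracer: degenerate column at the median
  expect_true(all(dev[, "B2"] == 4))
  # truncation to the observed range
  expect_true(all(dev[, "B1"] >= summ$min[1] & dev[, "B1"] <= summ$max[1]))

  # stratum coverage: mapping draws back through the truncated-normal CDF
  # must land exactly one draw in each of the 64 equal strata
  mu <- summ$median[1]; sg <- summ$qn[1]
  plo <- pnorm((summ$min[1] - mu) / sg); phi <- pnorm((summ$max[1] - mu) / sg)
  u <- (pnorm((dev[, "B1"] - mu) / sg) - plo) / (phi - plo)
  expect_equal(sort(floor(u * 64 - 1e-12)), 0:63)

  # moments of many draws against the truncated-normal closed form
  big <- suppressWarnings(sample_deviates(summ, 10000, seed = 9))[, "B1"]
  a <- (summ$min[1] - mu) / sg; b <- (summ$max[1] - mu) / sg
  Z <- pnorm(b) - pnorm(a)
  m_tr <- mu + sg * (dnorm(a) - dnorm(b)) / Z
  v_tr <- sg^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_equal(mean(big), m_tr, tolerance = 0.01 * abs(m_tr))
  expect_equal(sd(big), sqrt(v_tr), tolerance = 0.02 * sqrt(v_tr))
})

test_that("posterior distributions are normalized and R is their mean", {
  d <- posterior_distribution(c(0.5, 0.5, 0.5), "farmyard", n_bins = 100)
  expect_equal(sum(d$frequencies), 1)
  expect_equal(weighted_mean_R(d), 0.505)  # midvalue of the bin holding 0.5
  expect_equal(d$R, weighted_mean_R(d))

  u <- posterior_distribution(seq(0.005, 0.995, by = 0.01), n_bins = 100)
  expect_equal(weighted_mean_R(u), 0.5)  # uniform mass is symmetric

  set.seed(77)
  x <- runif(500)
  dx <- posterior_distribution(x, n_bins = 100)
  expect_equal(weighted_mean_R(dx),
               sum(dx$midvalues * dx$frequencies), tolerance = 1e-12)
  expect_gte(dx$R, dx$full_range[1])
  expect_lte(dx$R, dx$full_range[2])

  bad <- dx; bad$frequencies <- bad$frequencies * 2
  expect_error(weighted_mean_R(bad), "not normalized")
})

test_that("degenerate Monte Carlo (all Qn zero) collapses to the point
           solution", {
  panel <- small_panel(5)
  set.seed(30)
  s <- matrix(runif(20, 2, 10), 4, 5)
  # identical samples per category: zero spread everywhere
  src <- make_samples(s[rep(1:4, each = 2), ], "source",
                      rep(source_categories(), each = 2), panel = panel)
  p_true <- c(0.4, 0.3, 0.2, 0.1)
  sed <- make_samples(matrix(drop(p_true %*% s), 2, 5, byrow = TRUE),
                      "sediment", panel = panel)
  sig <- composite_signature("KW-H", panel$names,
                             separable_sources(n_per = 2, n_tracers = 5,
                                               seed = 1))
  src_sum <- source_summaries(src)
  sed_sum <- summarize_group(sed)
  mc <- suppressWarnings(run_monte_carlo(sig, src_sum, sed_sum,
                                         mc_config(n_accept = 50, seed = 3)))
  # every accepted solution is the single deterministic solve
  expect_equal(max(apply(mc$accepted, 2, function(v) diff(range(v)))), 0)
  det_sol <- solve_mixing(mixing_problem(panel$names, source_categories(),
                                         drop(p_true %*% s), s))
  for (cat in source_categories()) {
    # R sits at the midvalue of the bin holding the point solution:
    # agreement within one bin width
    expect_lt(abs(unname(mc$R[cat]) - unname(det_sol$p[cat])), 0.01)
  }
})

test_that("Monte Carlo accepts on GOF, reproduces bit-identically, and a
           zero threshold disables the filter", {
  model <- source_model(panel = small_panel(8), n_samples = 6, cv = 0.1)
  src <- generate_sources(model, seed = 41, subcatchment = "A")
  des <- mixture_design(c(0.35, 0.3, 0.2, 0.15))
  sed <- generate_sediment(model, des, seed = 42, sources = src,
                           subcatchment = "A")
  sig <- composite_signature("KW-H", tracer_names(src), src)
  src_sum <- source_summaries(src)
  sed_sum <- summarize_group(sed)

  cfg <- mc_config(n_accept = 120, seed = 8)
  mc1 <- suppressWarnings(run_monte_carlo(sig, src_sum, sed_sum, cfg))
  expect_true(all(mc1$gof > cfg$gof_threshold))
  for (d in mc1$posteriors) expect_equal(sum(d$frequencies), 1)
  expect_equal(rowSums(mc1$accepted), rep(1, nrow(mc1$accepted)),
               tolerance = 1e-9)

  mc2 <- suppressWarnings(run_monte_carlo(sig, src_sum, sed_sum, cfg))
  expect_identical(mc1$accepted, mc2$accepted)
  expect_identical(mc1$gof, mc2$gof)

  cfg0 <- mc_config(n_accept = 60, gof_threshold = 0, seed = 8)
  mc0 <- suppressWarnings(run_monte_carlo(sig, src_sum, sed_sum, cfg0))
  expect_equal(mc0$n_draws_used, 60L)  # acceptance rate 100%

  # an impossible threshold errors with the best GOF seen
  cfg_hi <- mc_config(n_accept = 10, gof_threshold = 0.999999,
                      max_draws = 40, seed = 8)
  expect_error(suppressWarnings(
    run_monte_carlo(sig, src_sum, sed_sum, cfg_hi)), "best GOF")
})

test_that("Monte Carlo recovers known mixture proportions", {
  model <- source_model(n_samples = 8, cv = 0.08, separation = 1)
  src <- generate_sources(model, seed = 11, subcatchment = "A")
  des <- mixture_design(c(0.5, 0.3, 0.15, 0.05), sediment_noise_cv = 0.02)
  sed <- generate_sediment(model, des, seed = 12, sources = src,
                           subcatchment = "A")
  cand <- passing_tracers(bracket_test(src, sed, model$panel))
  sig <- composite_signature("KW-H", cand, src)
  mc <- suppressWarnings(run_monte_carlo(
    sig, source_summaries(src), summarize_group(sed),
    mc_config(n_accept = 500, seed = 5)))
  expect_lt(max(abs(mc$R - des$true_p)), 0.1)
})

test_that("cross-signature combination reproduces the published worked
           examples under equal weights", {
  as_res <- function(R) list(R = c(farmyard = R), mean_gof = NA_real_,
                             overall_pct = NA_real_)
  # equal-weight combinations of the five per-signature medians
  comb <- combine_signatures(lapply(c(0.29, 0.29, 0.54, 0.67, 0.67), as_res))
  expect_equal(unname(comb), 0.49)
  comb2 <- combine_signatures(lapply(c(0.55, 0.58, 0.76, 0.58, 0.72), as_res))
  expect_equal(unname(comb2), 0.64)

  # single signature: identity
  one <- combine_signatures(list(list(R = c(a = 0.37, b = 0.63),
                                      mean_gof = 0.9, overall_pct = 100)))
  expect_equal(unname(one), c(0.37, 0.63))

  # explicit GOF x discrimination weighting
  res <- list(list(R = c(a = 0.2), mean_gof = 0.9, overall_pct = 100),
              list(R = c(a = 0.6), mean_gof = 0.95, overall_pct = 50))
  a1 <- 0.9 * 100; a2 <- 0.95 * 50
  expect_equal(unname(combine_signatures(res)),
               round((a1 * 0.2 + a2 * 0.6) / (a1 + a2), 2))

  expect_error(combine_signatures(list()), "empty")
})

test_that("catchment summary averages subcatchment contributions as
           percentages", {
  farm <- c(0.49, 0.25, 0.19, 0.64, 0.33, 0.27)
  road <- c(0.12, 0.05, 0.10, 0.07, 0.04, 0.35)
  per_sc <- lapply(1:6, function(i) c(farmyard = farm[i], road_verge = road[i]))
  names(per_sc) <- paste0("sc", 1:6)
  out <- catchment_summary(per_sc)
  expect_equal(round(unname(out["farmyard"])), 36)
  expect_equal(round(unname(out["road_verge"])), 12)

  same <- catchment_summary(list(a = c(x = 0.4), b = c(x = 0.4)))
  expect_equal(unname(same), 40)
})
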