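test_that("discriminatory weightings are ratios to the weakest tracer", {
  # published worked examples: five-tracer signature percentages
  w <- tdw(c(97, 96, 88, 100, 94))
  expect_equal(w, c(1.10, 1.09, 1.00, 1.14, 1.07))
  expect_equal(w[4], 1.14)  # the 100% tracer
  expect_equal(w[5], 1.07)  # the 94% tracer
  expect_equal(tdw(c(100, 88)), c(1.14, 1.00))
  expect_equal(tdw(c(94, 88)), c(1.07, 1.00))
  expect_equal(tdw(c(80, 80, 80)), c(1, 1, 1))
  expect_equal(min(tdw(c(56, 69, 88, 96, 97))), 1.00)
  expect_error(tdw(numeric(0)), "empty")
  expect_error(tdw(c(50, 0)), "0, 100")
  expect_error(tdw(c(50, 101)), "0, 100")
})

test_that("classification rate is 100% for separable categories and near
           chance for identical ones", {
  src <- separable_sources()
  expect_equal(classify_rate(src, "B1"), 100)
  expect_equal(classify_rate(src, c("B1", "B2")), 100)

  # identical distributions: resubstitution accuracy fluctuates around
  # chance; its mean over replicates stays near 50% for two categories
  panel <- small_panel(1)
  accs <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    vals <- matrix(rnorm(200), ncol = 1)
    tab <- make_samples(vals, "source",
                        rep(c("farmyard", "septic"), each = 100),
                        panel = panel)
    classify_rate(tab, "B1")
  }, numeric(1))
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("a five-tracer fixture built for full separation classifies 100%", {
  # synthetic analogue of a subcatchment whose final composite signature
  # correctly classifies every source sample
  src <- separable_sources(n_per = 8, n_tracers = 5, sd = 0.5, seed = 21)
  sig <- composite_signature("GA-DFA", tracer_names(src), src)
  expect_equal(sig$overall_pct, 100)
  expect_equal(min(sig$tdw), 1.00)
  expect_true(all(sig$tdw >= 1))
})

test_that("GA-DFA matches the exhaustive subset oracle on a 6-tracer fixture", {
  # tracers B1, B2 jointly separate the 4 categories; B3..B6 are pure noise
  set.seed(13)
  panel <- small_panel(6)
  cats <- source_categories()
  n_per <- 6L
  # individually each informative tracer splits the categories 2-2; only
  # jointly do B1 and B2 give full separation
  lev1 <- c(10, 10, 20, 20); lev2 <- c(10, 20, 10, 20)
  informative <- do.call(rbind, lapply(1:4, function(k) {
    cbind(rnorm(n_per, lev1[k], 0.4), rnorm(n_per, lev2[k], 0.4))
  }))
  noise <- matrix(rnorm(4 * n_per * 4), ncol = 4)
  src <- make_samples(cbind(informative, noise), "source",
                      rep(cats, each = n_per), panel = panel)

  ga <- select_ga_dfa(src, panel$names, n_repeats = 3, seed = 5)
  top <- ga[[1]]
  expect_equal(top$overall_pct, 100)

  # oracle: enumerate all 63 non-empty subsets with the same feasibility
  # rule and ranking
  subsets <- lapply(1:63, function(b) panel$names[bitwAnd(b, 2^(0:5)) > 0])
  feasible <- Filter(function(s) omfingr:::subset_entry_valid(src, s, 0.05),
                     subsets)
  expect_gt(length(feasible), 0)
  acc <- vapply(feasible, function(s) classify_rate(src, s), numeric(1))
  lam <- vapply(feasible, function(s) wilks_lambda(src, s), numeric(1))
  sizes <- lengths(feasible)
  lex <- vapply(feasible, function(s) paste(s, collapse = "\001"), character(1))
  best <- feasible[[order(-acc, lam, sizes, lex)[1]]]
  expect_setequal(top$tracers, best)
  # the winning subset must rely on the informative pair
  expect_true(all(c("B1", "B2") %in% top$tracers))

  # distinct signatures, reproducible under a fixed seed
  keys <- vapply(ga, function(s) paste(sort(s$tracers), collapse = "+"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  ga2 <- select_ga_dfa(src, panel$names, n_repeats = 3, seed = 5)
  expect_identical(lapply(ga, `[[`, "tracers"), lapply(ga2, `[[`, "tracers"))

  # single-candidate degenerate case
  one <- select_ga_dfa(src, "B1", n_repeats = 1, seed = 1)
  expect_equal(one[[1]]$tracers, "B1")
  expect_equal(unname(one[[1]]$tdw), 1.00)
})

test_that("Kruskal-Wallis selection ranks by H and grows monotonically", {
  # hand-computed H for two groups {1,2,3} vs {7,8,9}: rank sums 6 and 15,
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1) = 3.857142857
  h <- kruskal.test(c(1, 2, 3, 7, 8, 9),
                    factor(rep(c("a", "b"), each = 3)))$statistic
  expect_equal(unname(h), 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)

  # one discriminating tracer among constants-plus-noise
  set.seed(17)
  panel <- small_panel(4)
  cats <- source_categories()
  n_per <- 6L
  vals <- cbind(rep(10 * 1:4, each = n_per) + rnorm(24, 0, 0.2),
                matrix(rnorm(24 * 3, 5, 0.01), ncol = 3))
  src <- make_samples(vals, "source", rep(cats, each = n_per), panel = panel)
  sig <- select_kw_h(src, panel$names, min_size = 1)
  expect_equal(sig$tracers[1], "B1")
  expect_equal(sig$method, "KW-H")

  # growth: classification of the final signature dominates its prefixes
  src2 <- separable_sources(n_per = 8, n_tracers = 6, sd = 2.5, seed = 33)
  sig2 <- select_kw_h(src2, tracer_names(src2), min_size = 3)
  accs <- vapply(seq_along(sig2$tracers), function(k) {
    classify_rate(src2, sig2$tracers[seq_len(k)])
  }, numeric(1))
  expect_true(all(sig2$overall_pct >= accs))

  const <- make_samples(matrix(5, 12, 1), "source",
                        rep(cats[1:2], each = 6), panel = small_panel(1))
  expect_error(select_kw_h(const, "B1"), "significant")
})

test_that("PCA ranking agrees with an eigen-decomposition oracle", {
  set.seed(23)
  panel <- small_panel(5)
  n <- 24L
  # rank-2 latent structure plus one dominant tracer
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(5 * f1, 2 * f1 + 2 * f2, f2, 0.6 * f1 - 0.3 * f2,
             0.4 * f2 + 0.2 * f1)
  src <- make_samples(X + rnorm(n * 5, 0, 0.01), "source",
                      rep(source_categories(), each = 6), panel = panel)
  sig <- select_pca(src, panel$names, n_components = 2, min_size = 3)
  expect_equal(sig$method, "PCA")
  # two components capture a rank-2 matrix almost entirely
  expect_gt(sum(sig$explained), 0.99)

  # oracle: eigenvectors of the correlation matrix
  Xs <- scale(as.matrix(src[, panel$names]))
  ev <- eigen(cor(as.matrix(src[, panel$names])))
  oracle_load <- ev$vectors[, 1:2]
  oracle_rank <- panel$names[order(-apply(abs(oracle_load), 1, max))]
  got_rank <- names(sort(apply(abs(sig$loadings), 1, max), decreasing = TRUE))
  expect_equal(got_rank, oracle_rank)

  expect_error(select_pca(src, "B1", n_components = 2), "fewer tracers")
})

test_that("every selection route yields TDW floored at exactly 1", {
  src <- separable_sources(n_per = 6, n_tracers = 6, sd = 2.8, seed = 55)
  cand <- tracer_names(src)
  sigs <- c(select_ga_dfa(src, cand, n_repeats = 2, seed = 9),
            list(select_kw_h(src, cand), select_pca(src, cand)))
  for (sig in sigs) {
    expect_equal(min(sig$tdw), 1.00)
    expect_true(all(sig$tdw >= 1))
    expect_equal(unname(sig$tdw),
                 unname(round(sig$classification_pct /
                                min(sig$classification_pct), 2)))
  }
})
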