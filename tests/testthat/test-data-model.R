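test_that("tracer tables parse, validate and round-trip", {
  panel <- small_panel(2)
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,role,category,subcatchment,B1,B2",
               "s1,source,farmyard,A,1.5,2.5",
               "s2,source,road_verge,A,2.0,3.0",
               "m1,sediment,,A,1.75,2.75"), csv)
  tab <- read_tracer_table(csv, panel)
  expect_equal(nrow(tab), 3L)
  expect_equal(tracer_names(tab), c("B1", "B2"))
  expect_equal(tab$B1, c(1.5, 2.0, 1.75))
  expect_true(is.na(tab$category[3]))

  # a sediment record carrying a category violates the record invariants
  writeLines(c("sample_id,role,category,subcatchment,B1,B2",
               "m1,sediment,farmyard,A,1.0,2.0"), csv)
  expect_error(read_tracer_table(csv, panel), "sediment record carries")

  # schema and parse errors name the offender
  writeLines(c("sample_id,role,category,B1,B2",
               "s1,source,farmyard,1.0,2.0"), csv)
  expect_error(read_tracer_table(csv, panel), "subcatchment")
  writeLines(c("sample_id,role,category,subcatchment,B1,B2",
               "s1,source,farmyard,A,oops,2.0"), csv)
  expect_error(read_tracer_table(csv, panel), "row 1, column 'B1'")
  writeLines(c("sample_id,role,category,subcatchment,B1,B2",
               "s1,source,cowshed,A,1.0,2.0"), csv)
  expect_error(read_tracer_table(csv, panel), "unknown source category")
})

test_that("generator output round-trips through write and read unchanged", {
  model <- source_model(panel = small_panel(4), n_samples = 3)
  src <- generate_sources(model, seed = 3, subcatchment = "A")
  path <- tempfile(fileext = ".csv")
  write_tracer_table(src, path)
  back <- read_tracer_table(path, model$panel)
  for (tc in tracer_names(src)) expect_equal(back[[tc]], src[[tc]])
  expect_equal(back$sample_id, src$sample_id)
  # and a second round trip is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_tracer_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("replicate averaging reduces each group to its per-tracer mean", {
  panel <- small_panel(2)
  vals <- rbind(c(1, 10), c(2, 20), c(3, 30),  # s1 triplicate
                c(5, 50))                      # s2 single
  tab <- make_samples(vals, "source", "farmyard", panel = panel,
                      ids = c("s1", "s1", "s1", "s2"),
                      replicate_index = c(1L, 2L, 3L, 1L))
  avg <- average_replicates(tab)
  expect_equal(nrow(avg), 2L)
  expect_equal(avg$B1, c(2, 5))
  expect_equal(avg$B2, c(20, 50))
  expect_equal(avg$replicate_index, c(1L, 1L))

  # brute-force oracle on a random 3-replicate fixture
  set.seed(42)
  vr <- matrix(rnorm(12), nrow = 6)
  rt <- make_samples(vr, "source", "septic", panel = panel,
                     ids = rep(c("a", "b"), each = 3),
                     replicate_index = rep(1:3, 2))
  av <- average_replicates(rt)
  expect_equal(av$B1, c(mean(vr[1:3, 1]), mean(vr[4:6, 1])))
  expect_equal(av$B2, c(mean(vr[1:3, 2]), mean(vr[4:6, 2])))

  # replicates disagreeing on category are rejected
  bad <- make_samples(vals[1:2, ], "source", c("farmyard", "septic"),
                      panel = panel, ids = c("s1", "s1"),
                      replicate_index = 1:2)
  expect_error(average_replicates(bad), "disagree")
})

test_that("group summaries match brute-force statistics and invariants", {
  panel <- small_panel(1)
  tab <- make_samples(matrix(c(2, 4, 6), 3), "sediment", panel = panel)
  s <- summarize_group(tab)
  expect_equal(s$median, 4)
  expect_equal(s$min, 2)
  expect_equal(s$max, 6)
  expect_equal(s$n, 3)

  # identical values: degenerate scale and CV
  tab0 <- make_samples(matrix(5, 4, 1), "sediment", panel = panel)
  s0 <- summarize_group(tab0)
  expect_equal(s0$qn, 0)
  expect_equal(s0$cv, 0)

  # n = 25 normal draws against direct recomputation
  set.seed(99)
  v <- rnorm(25, 10, 2)
  s25 <- summarize_group(make_samples(matrix(v, 25), "sediment",
                                      panel = panel))
  expect_equal(s25$median, median(v))
  expect_equal(s25$cv, sd(v) / mean(v))
  expect_equal(s25$mean, mean(v))

  # permutation invariance and median-in-range, across random groups
  for (k in 1:5) {
    set.seed(k)
    v <- rnorm(8, 3, 1)
    t1 <- make_samples(matrix(v, 8), "sediment", panel = panel)
    t2 <- make_samples(matrix(v[sample(8)], 8), "sediment", panel = panel)
    s1 <- summarize_group(t1); s2 <- summarize_group(t2)
    expect_equal(s1$median, s2$median)
    expect_equal(s1$qn, s2$qn)
    expect_gte(s1$median, s1$min)
    expect_lte(s1$median, s1$max)
  }

  expect_error(summarize_group(tab[0, ]), "empty")
})

test_that("SV weights invert the CV with a neutral fallback at zero mean", {
  panel <- small_panel(2)
  set.seed(5)
  # second tracer centred on zero => undefined CV
  vals <- cbind(rnorm(6, 10, 1), c(-1, 1, -2, 2, -0.5, 0.5))
  tab <- make_samples(vals, "source", "farmyard", panel = panel)
  s <- summarize_group(tab)
  expect_true(is.finite(s$cv[1]))
  expect_warning(sv <- sv_weights(s), "neutral weight")
  expect_equal(unname(sv["B1"]), 1 / s$cv[1])
  expect_equal(unname(sv["B2"]), 1)
})

test_that("oxygen tables round-trip per flask", {
  inc <- generate_incubation(6, dry_mass_g = 2, temperature_c = 15,
                             dt_days = 2.5)
  path <- tempfile(fileext = ".csv")
  write_oxygen_table(list(inc$sample, inc$blank), path)
  back <- read_oxygen_table(path)
  expect_named(back, c("F1", "F1_blank"))
  expect_equal(back$F1$o2_mass, inc$sample$o2_mass)
  expect_equal(back$F1$dry_mass_g, 2)
  expect_true(back$F1_blank$is_blank)
})
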