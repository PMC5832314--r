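# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

small_panel <- function(n = 6L, prefix = "B") {
  tracer_panel(paste0(prefix, seq_len(n)), kind = "isotope")
}

# Assemble a validated sample_table from a value matrix (rows = samples).
make_samples <- function(values, role, category = NA_character_,
                         subcatchment = "T", panel,
                         ids = NULL, replicate_index = 1L) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(ids)) ids <- sprintf("%s_%02d", role, seq_len(n))
  df <- data.frame(sample_id = ids, role = role,
                   category = rep_len(category, n),
                   subcatchment = subcatchment,
                   replicate_index = rep_len(replicate_index, n),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[panel$names[seq_len(ncol(values))]] <-
    as.data.frame(values, check.names = FALSE)
  validate_sample_table(df, panel)
}

# Four categories fully separated on every tracer: category k lives near
# level 10*k with small scatter.
separable_sources <- function(n_per = 6L, n_tracers = 5L, sd = 0.3,
                              seed = 7L, panel = small_panel(n_tracers)) {
  set.seed(seed)
  cats <- source_categories()
  vals <- do.call(rbind, lapply(seq_along(cats), function(k) {
    matrix(stats::rnorm(n_per * n_tracers, 10 * k, sd), nrow = n_per)
  }))
  make_samples(vals, "source", rep(cats, each = n_per), panel = panel,
               ids = sprintf("src_%s_%02d", rep(cats, each = n_per),
                             rep(seq_len(n_per), length(cats))))
}

# Per-category summaries in canonical category order.
source_summaries <- function(src) {
  out <- lapply(split(as.data.frame(src), src$category), function(d) {
    attr(d, "tracers") <- tracer_names(src)
    class(d) <- c("sample_table", "data.frame")
    suppressWarnings(summarize_group(d))
  })
  out[intersect(source_categories(), names(out))]
}

# Random well-posed mixing problem with an exact mixture sediment vector.
random_problem <- function(m = 3L, n = 5L, seed = 1L, sv = NULL, w = NULL) {
  set.seed(seed)
  s <- matrix(stats::runif(m * n, 1, 10), m, n)
  p_true <- as.numeric(stats::rgamma(m, 2)); p_true <- p_true / sum(p_true)
  c_vec <- drop(p_true %*% s)
  list(problem = mixing_problem(paste0("t", seq_len(n)),
                                paste0("cat", seq_len(m)),
                                c_vec, s, sv = sv, w = w),
       p_true = p_true)
}

# All compositions of the m-simplex at the given grid resolution.
simplex_grid <- function(m, step = 0.01) {
  k <- round(1 / step)
  if (m == 2L) {
    i <- 0:k
    return(cbind(i, k - i) / k)
  }
  if (m == 3L) {
    g <- expand.grid(i = 0:k, j = 0:k)
    g <- g[g$i + g$j <= k, ]
    return(cbind(g$i, g$j, k - g$i - g$j) / k)
  }
  g <- expand.grid(i = 0:k, j = 0:k, l = 0:k)
  g <- g[g$i + g$j + g$l <= k, ]
  cbind(g$i, g$j, g$l, k - g$i - g$j - g$l) / k
}

# Independent vectorized evaluation of the default objective over a matrix
# of proportion rows (used as the grid-search oracle).
grid_objective <- function(problem, P, literal_eq3 = FALSE) {
  chat <- P %*% (if (literal_eq3) problem$s * problem$sv else problem$s)
  r <- sweep(-sweep(chat, 2, problem$c), 2, problem$c, "/")
  if (literal_eq3) {
    drop(r^2 %*% problem$w)
  } else {
    svbar <- P %*% problem$sv
    rowSums(sweep(r^2 * svbar, 2, problem$w, "*"))
  }
}
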