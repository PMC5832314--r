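#' Construct a mixing problem
#'
#' The weighted mass-balance problem: find source proportions P minimizing
#' the sum of squared weighted relative errors between the measured sediment
#' tracer medians C_i and the mixture predictions sum_s P_s S_si. Two
#' weightings enter the objective: SV_si, the within-source variability
#' weighting (inverse coefficient of variation), and W_i, the tracer
#' discriminatory weighting of the composite signature.
#'
#' @param tracers ordered tracer names (length n).
#' @param categories ordered source category names (length m).
#' @param c numeric vector of sediment medians C_i (all non-zero).
#' @param s m x n matrix of source medians S_si.
#' @param sv m x n matrix of within-source weights SV_si (default all 1).
#' @param w length-n vector of tracer discriminatory weights W_i (>= 1).
#' @return a `mixing_problem`.
#' @export
mixing_problem <- function(tracers, categories, c, s, sv = NULL, w = NULL) {
  n <- length(tracers); m <- length(categories)
  s <- matrix(s, nrow = m, ncol = n, dimnames = list(categories, tracers))
  if (is.null(sv)) sv <- matrix(1, m, n)
  sv <- matrix(sv, nrow = m, ncol = n, dimnames = list(categories, tracers))
  if (is.null(w)) w <- rep(1, n)
  w <- stats::setNames(as.numeric(w), tracers)
  c <- stats::setNames(as.numeric(c), tracers)
  if (length(c) != n) stop("mixing_problem: length(c) != number of tracers", call. = FALSE)
  if (any(c == 0)) {
    stop("mixing_problem: sediment median C_i = 0 for tracer(s) ",
         paste(tracers[c == 0], collapse = ", "),
         "; exclude these tracers from the signature", call. = FALSE)
  }
  if (any(!is.finite(c)) || any(!is.finite(s)) || any(!is.finite(sv)) ||
      any(!is.finite(w))) {
    stop("mixing_problem: non-finite inputs", call. = FALSE)
  }
  if (any(w < 1)) stop("mixing_problem: discriminatory weights must be >= 1", call. = FALSE)
  if (any(sv < 0)) stop("mixing_problem: SV weights must be >= 0", call. = FALSE)
  structure(list(tracers = tracers, categories = categories,
                 c = c, s = s, sv = sv, w = w, n = n, m = m),
            class = "mixing_problem")
}

#' Mixing-model objective
#'
#' Default form: `sum_i W_i * SVbar_i(p) * ((C_i - sum_s p_s S_si)/C_i)^2`
#' with `SVbar_i(p) = sum_s p_s SV_si`, i.e. SV acts as a weight on each
#' squared relative error (collapsed to tracer level as the
#' proportion-weighted mean across sources), so predicted mixture
#' concentrations remain mass-conserving. With `literal_eq3 = TRUE` the SV
#' weight instead multiplies S_si inside the predicted concentration,
#' `sum_i W_i ((C_i - sum_s p_s S_si SV_si)/C_i)^2`, which distorts the
#' predictions and is kept only for fidelity comparisons.
#'
#' @param problem a [mixing_problem()].
#' @param p proportion vector on the simplex (length m).
#' @param literal_eq3 logical, see Details.
#' @return non-negative objective value.
#' @export
mixing_objective <- function(problem, p, literal_eq3 = FALSE) {
  stopifnot(inherits(problem, "mixing_problem"))
  p <- as.numeric(p)
  if (length(p) != problem$m) stop("mixing_objective: wrong p length", call. = FALSE)
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("mixing_objective: p must lie on the simplex", call. = FALSE)
  }
  if (literal_eq3) {
    chat <- drop(crossprod(problem$s * problem$sv, p))
    r <- (problem$c - chat) / problem$c
    sum(problem$w * r^2)
  } else {
    chat <- drop(crossprod(problem$s, p))
    svbar <- drop(crossprod(problem$sv, p))
    r <- (problem$c - chat) / problem$c
    sum(problem$w * svbar * r^2)
  }
}

# Objective and gradient in the squared parametrization p = x^2 / sum(x^2),
# which maps unconstrained x onto the closed simplex (vertices reachable).
obj_grad_x <- function(problem, x, literal_eq3) {
  q <- x^2
  Tt <- sum(q)
  p <- q / Tt
  s_eff <- if (literal_eq3) problem$s * problem$sv else problem$s
  chat <- drop(crossprod(s_eff, p))
  r <- (problem$c - chat) / problem$c
  if (literal_eq3) {
    f <- sum(problem$w * r^2)
    # df/dp_s = sum_i w_i * 2 r_i * (-s_eff[s,i]/c_i)
    gp <- drop(s_eff %*% (-2 * problem$w * r / problem$c))
  } else {
    svbar <- drop(crossprod(problem$sv, p))
    f <- sum(problem$w * svbar * r^2)
    gp <- drop(problem$sv %*% (problem$w * r^2)) +
      drop(problem$s %*% (-2 * problem$w * svbar * r / problem$c))
  }
  gx <- (2 * x / Tt) * (gp - sum(gp * p))
  list(f = f, g = gx, p = p)
}

#' Solve the mixing problem for source proportions
#'
#' Minimizes [mixing_objective()] over the proportion simplex
#' (p >= 0, sum p = 1). The simplex is parametrized as p = x^2/||x||^2 and
#' the smooth unconstrained problem is solved with `stats::nlminb` and an
#' analytic gradient, from deterministic multi-starts: the centroid plus
#' each slightly-smoothed vertex. The best local solution is kept, so the
#' solver is deterministic given the problem.
#'
#' Near-duplicate source rows make the solution non-unique; the result is
#' then still a valid simplex point but is flagged via the `nonunique`
#' element and a warning.
#'
#' @param problem a [mixing_problem()].
#' @param literal_eq3 logical, see [mixing_objective()].
#' @return a `source_proportions` list: `p` (named, sums to 1 within 1e-9),
#'   `objective`, `gof`, `nonunique`, `starts` (objective per start).
#' @export
solve_mixing <- function(problem, literal_eq3 = FALSE) {
  stopifnot(inherits(problem, "mixing_problem"))
  m <- problem$m
  if (m < 2L) stop("solve_mixing: need >= 2 categories", call. = FALSE)
  eps <- 0.1
  starts <- rbind(rep(1 / m, m),
                  (1 - eps) * diag(m) + eps / m)
  best <- NULL
  start_obj <- numeric(nrow(starts))
  for (k in seq_len(nrow(starts))) {
    x0 <- sqrt(starts[k, ])
    fit <- stats::nlminb(
      x0,
      objective = function(x) obj_grad_x(problem, x, literal_eq3)$f,
      gradient = function(x) obj_grad_x(problem, x, literal_eq3)$g,
      control = list(iter.max = 500, eval.max = 1000))
    p <- fit$par^2 / sum(fit$par^2)
    # snap negligible components to the simplex face and re-evaluate
    p[p < 1e-12] <- 0
    p <- p / sum(p)
    obj <- mixing_objective(problem, p, literal_eq3)
    start_obj[k] <- obj
    if (is.null(best) || obj < best$objective) {
      best <- list(p = p, objective = obj)
    }
  }
  if (is.null(best) || !is.finite(best$objective)) {
    stop("solve_mixing: no start converged; objectives: ",
         paste(signif(start_obj, 4), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated_source_rows(problem)
  if (dup) {
    warning("solve_mixing: near-duplicate source categories; ",
            "proportions are non-unique", call. = FALSE)
  }
  structure(list(p = stats::setNames(best$p, problem$categories),
                 objective = best$objective,
                 gof = mixing_gof(problem, best$p),
                 nonunique = dup,
                 starts = start_obj),
            class = "source_proportions")
}

duplicated_source_rows <- function(problem) {
  s <- problem$s / pmax(abs(problem$c[col(problem$s)]), .Machine$double.eps)
  m <- problem$m
  for (a in seq_len(m - 1)) for (b in seq((a + 1), m)) {
    if (max(abs(s[a, ] - s[b, ])) < 1e-10) return(TRUE)
  }
  FALSE
}

#' Goodness of fit of a proportion vector
#'
#' One minus the absolute mean relative error between the mixture-predicted
#' and measured sediment tracer values:
#' `GOF = 1 - (1/n) sum_i |C_i - Chat_i(p)| / |C_i|` with
#' `Chat_i(p) = sum_s p_s S_si`. Unweighted — the acceptance test of the
#' Monte Carlo runs is a separate check from the weighted objective.
#' Clamped below at 0.
#'
#' @param problem a [mixing_problem()].
#' @param p proportion vector on the simplex.
#' @return GOF in \[0, 1\].
#' @export
mixing_gof <- function(problem, p) {
  stopifnot(inherits(problem, "mixing_problem"))
  p <- as.numeric(p)
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("mixing_gof: p must lie on the simplex", call. = FALSE)
  }
  chat <- drop(crossprod(problem$s, p))
  amre <- mean(abs(problem$c - chat) / abs(problem$c))
  max(0, 1 - amre)
}

#' @export
print.source_proportions <- function(x, ...) {
  cat("<source_proportions> objective ", signif(x$objective, 4),
      ", GOF ", signif(x$gof, 4), "\n", sep = "")
  print(round(x$p, 4))
  invisible(x)
}
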