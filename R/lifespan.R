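#' Random-walk model of gene lifespan
#'
#' Constructs the parameter object for the gambler's-ruin model of gene
#' loss.  A gene starts at relative fitness 1; each fixed mutation moves its
#' fitness up (+s, with probability `alpha`) or down (-s).  The gene is lost
#' (pseudogenized or deleted) when `k` more deleterious than beneficial
#' mutations have fixed, i.e. when fitness first reaches `1 - k*s`.  `alpha`
#' here is the fraction of *fixed* substitutions that are beneficial, not
#' the fraction of new mutations.
#'
#' @param alpha Fraction of fixed substitutions that are beneficial, in
#'   `[0, 1)`.  A finite expected lifespan requires `alpha < 1/2`.
#' @param k Loss threshold in net deleterious fixations, positive integer.
#' @param r_b,r_d Optional fixation rates (per unit time) of beneficial and
#'   deleterious mutations; needed by [expected_extinction_time()].  When
#'   both are supplied, `alpha` may be omitted and defaults to
#'   `r_b / (r_b + r_d)`; if supplied it must be consistent with the rates.
#' @return An object of class `walk_model`.
#' @examples
#' w <- walk_model(alpha = 0.25, k = 3)
#' expected_substitutions(w)   # 6: k / (1 - 2 alpha)
#' @export
walk_model <- function(alpha = NULL, k, r_b = NULL, r_d = NULL) {
  if (!is.numeric(k) || k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (!is.null(r_b) || !is.null(r_d)) {
    if (is.null(r_b) || is.null(r_d)) stop("supply both 'r_b' and 'r_d' or neither")
    if (r_b < 0 || r_d < 0 || r_b + r_d <= 0)
      stop("fixation rates must be >= 0 with r_b + r_d > 0")
    alpha_rates <- r_b / (r_b + r_d)
    if (is.null(alpha)) alpha <- alpha_rates
    else if (abs(alpha - alpha_rates) > 1e-8)
      stop("'alpha' inconsistent with r_b / (r_b + r_d)")
  }
  if (is.null(alpha)) stop("'alpha' is required when rates are not given")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1)")
  structure(list(alpha = alpha, k = as.integer(k), r_b = r_b, r_d = r_d),
            class = "walk_model")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("Gene-lifespan walk: alpha = %g, k = %d", x$alpha, x$k))
  if (!is.null(x$r_b)) cat(sprintf(", r_B = %g, r_D = %g", x$r_b, x$r_d))
  cat("\n")
  invisible(x)
}

#' Probability generating function of the number of substitutions at loss
#'
#' Evaluates `V(z) = [(1 - sqrt(1 - 4*alpha*(1-alpha)*z^2)) / (2*alpha*z)]^k`,
#' the PGF of the total number of substitutions fixed before the gene is
#' lost.  The dummy variable is named `z` (the literature often prints it
#' `s`, colliding with the selection coefficient).  `V(1)` is the
#' probability the gene is ever lost: 1 for `alpha <= 1/2`, and
#' `((1-alpha)/alpha)^k` otherwise.  At `alpha = 0` the walk is purely
#' downward and `V(z) = z^k`.
#'
#' @param model A [walk_model()] object (values of `alpha` up to 1 are
#'   accepted here even though the expected lifespan then diverges).
#' @param z PGF argument in `(0, 1]`; may be a vector.
#' @return `V(z)`, same length as `z`.
#' @export
extinction_pgf <- function(model, z) {
  stopifnot(inherits(model, "walk_model"))
  if (any(z <= 0 | z > 1)) stop("'z' must lie in (0, 1]")
  a <- model$alpha
  k <- model$k
  if (a == 0) return(z^k)
  disc <- 1 - 4 * a * (1 - a) * z^2
  ((1 - sqrt(pmax(disc, 0))) / (2 * a * z))^k
}

#' Expected number of substitutions before gene loss
#'
#' The mean of the PGF in [extinction_pgf()], obtained from its derivative
#' at 1: `n_T = k / (2^k * sqrt(1 - 4*alpha*(1-alpha))) *
#' ((1 - sqrt(1 - 4*alpha*(1-alpha))) / alpha)^k`.  For `alpha < 1/2` the
#' discriminant is `(1 - 2*alpha)^2`, so this simplifies algebraically to
#' `k / (1 - 2*alpha)`; the implementation evaluates the full expression
#' (with the pure-drift limit `k` at `alpha = 0`) and the simplification is
#' verified by the test suite.  For small `alpha` the first-order expansion
#' is `k * (1 + 2*alpha)`.
#'
#' @param model A [walk_model()] object with `alpha < 1/2`.
#' @return Expected number of substitutions (scalar).
#' @export
expected_substitutions <- function(model) {
  stopifnot(inherits(model, "walk_model"))
  a <- model$alpha
  k <- model$k
  if (a >= 0.5)
    stop("expected_substitutions: mean diverges for alpha >= 1/2")
  if (a == 0) return(as.numeric(k))
  root <- sqrt(1 - 4 * a * (1 - a))
  k / (2^k * root) * ((1 - root) / a)^k
}

#' Expected time to gene loss
#'
#' Converts the expected substitution count to calendar time using the
#' fixation rates.  Two variants are returned: the small-`alpha`
#' approximation `t = (k / (r_B + r_D)) * (1 + 2*r_B / (r_B + r_D))` (the
#' default, reported as `t_bar`) and the exact composition
#' `t_exact = n_T / (r_B + r_D) = k / ((r_B + r_D) * (1 - 2*alpha))`.
#' Stronger purifying selection lowers `r_D` and so lengthens a gene's
#' life; genes under weak purifying selection die young.
#'
#' @param model A [walk_model()] object carrying `r_b` and `r_d` with
#'   `r_b / (r_b + r_d) < 1/2`.
#' @return A list with `t_bar` (approximation), `t_exact`, and the `alpha`
#'   implied by the rates.
#' @export
expected_extinction_time <- function(model) {
  stopifnot(inherits(model, "walk_model"))
  if (is.null(model$r_b) || is.null(model$r_d))
    stop("expected_extinction_time requires fixation rates r_b and r_d")
  rb <- model$r_b; rd <- model$r_d
  if (rb + rd <= 0) stop("total fixation rate must be positive")
  a <- rb / (rb + rd)
  if (a >= 0.5)
    stop("expected_extinction_time: mean diverges for r_b / (r_b + r_d) >= 1/2")
  k <- model$k
  list(t_bar = (k / (rb + rd)) * (1 + 2 * rb / (rb + rd)),
       t_exact = expected_substitutions(walk_model(alpha = a, k = k)) / (rb + rd),
       alpha = a)
}

#' Monte-Carlo simulation of the gene-lifespan walk
#'
#' Simulates `n_draws` independent +/-1 random walks (up with probability
#' `alpha`) started at 0 and absorbed at `-k`, the direct stochastic
#' counterpart of [extinction_pgf()] and [expected_substitutions()].
#' Walks still unabsorbed after `max_steps` steps are censored and reported.
#'
#' @param model A [walk_model()] object.
#' @param n_draws Number of walks.
#' @param max_steps Censoring horizon (steps).
#' @param seed Integer RNG seed.
#' @return A list of class `walk_result`: `n_draws`, `mean_steps` and
#'   `se_steps` over absorbed walks, `absorbed_fraction`, `n_censored`.
#' @export
simulate_walk <- function(model, n_draws, max_steps = 1e7, seed = 1) {
  stopifnot(inherits(model, "walk_model"), n_draws >= 1)
  set.seed(seed)
  a <- model$alpha
  k <- model$k
  pos <- integer(n_draws)
  steps <- numeric(n_draws)
  active <- rep(TRUE, n_draws)
  n_steps <- 0
  while (any(active) && n_steps < max_steps) {
    n_steps <- n_steps + 1
    idx <- which(active)
    up <- stats::runif(length(idx)) < a
    pos[idx] <- pos[idx] + ifelse(up, 1L, -1L)
    done <- idx[pos[idx] == -k]
    if (length(done)) {
      steps[done] <- n_steps
      active[done] <- FALSE
    }
  }
  absorbed <- !active
  st <- steps[absorbed]
  structure(list(
    n_draws = n_draws,
    mean_steps = if (length(st)) mean(st) else NA_real_,
    se_steps = if (length(st) > 1) stats::sd(st) / sqrt(length(st)) else NA_real_,
    absorbed_fraction = mean(absorbed),
    n_censored = sum(active)
  ), class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf(
    "Walk simulation: %d draws, absorbed %.4f, mean steps %.4f (SE %.4f), censored %d\n",
    x$n_draws, x$absorbed_fraction, x$mean_steps, x$se_steps, x$n_censored))
  invisible(x)
}
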