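#' Parameters of the explosive microfailure process
#'
#' Bundles the two parameters of the strain-indexed microfailure process:
#' the rate ratio `alpha` between consecutive inter-event distributions and
#' the baseline rate `lambda` (units 1/strain). After the k-th microfailure
#' the strain increment to the next one is exponential with rate
#' \eqn{\lambda_k = \lambda \alpha^{-k+1}}; `alpha < 1` makes the rates grow
#' geometrically so that the process is explosive: the total strain
#' accumulated over infinitely many events is almost surely finite. The
#' derived deterioration rate \eqn{\beta = -\ln \alpha > 0} is the constant
#' per-event logarithmic growth of the hazard.
#'
#' @param alpha rate ratio, strictly between 0 and 1.
#' @param lambda baseline rate of the first increment, > 0, units 1/strain.
#'
#' @return An object of class `"coxplosive_params"`: a list with elements
#'   `alpha`, `lambda` and the derived `beta = -log(alpha)`.
#'
#' @examples
#' p <- coxplosive_params(alpha = 0.9, lambda = 50)
#' mu_infinity(p)      # expected total strain, 1/((1 - 0.9) * 50) = 0.2
#' deterioration_rate(p)
#' @export
coxplosive_params <- function(alpha, lambda) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1); got ", format(alpha),
         " (alpha >= 1 is the non-explosive regime)", call. = FALSE)
  if (lambda <= 0)
    stop("'lambda' must be > 0; got ", format(lambda), call. = FALSE)
  structure(list(alpha = alpha, lambda = lambda, beta = -log(alpha)),
            class = "coxplosive_params")
}

#' @export
print.coxplosive_params <- function(x, digits = 4, ...) {
  cat("Coxplosive process parameters\n")
  cat(sprintf("  alpha  = %s   (rate ratio)\n", format(x$alpha, digits = digits)))
  cat(sprintf("  lambda = %s   (1/strain)\n", format(x$lambda, digits = digits)))
  cat(sprintf("  beta   = %s   (deterioration rate, -log alpha)\n",
              format(x$beta, digits = digits)))
  cat(sprintf("  E(total strain) = %s\n", format(mu_infinity(x), digits = digits)))
  invisible(x)
}

as_coxplosive_params <- function(p) {
  if (inherits(p, "coxplosive_params")) return(p)
  if (is.numeric(p) && length(p) == 2L) return(coxplosive_params(p[[1L]], p[[2L]]))
  if (is.list(p) && all(c("alpha", "lambda") %in% names(p)))
    return(coxplosive_params(p$alpha, p$lambda))
  stop("cannot interpret 'params'; supply coxplosive_params() or c(alpha, lambda)",
       call. = FALSE)
}

#' Hazard rate of the k-th strain increment
#'
#' The exponential rate governing the strain increment between the
#' (k-1)-th and k-th microfailure: \eqn{\lambda_k = \lambda \alpha^{-k+1}}.
#' Strictly increasing in k for `alpha < 1` -- each microfailure embrittles
#' the material and shortens the expected wait (in strain) to the next one.
#'
#' @param k event index, integer >= 1 (vectorized).
#' @param params a [coxplosive_params()] object (or coercible).
#' @return Rate(s) \eqn{\lambda_k}, units 1/strain.
#' @examples
#' event_rate(1:3, coxplosive_params(0.5, 2))  # 2, 4, 8
#' @export
event_rate <- function(k, params) {
  params <- as_coxplosive_params(params)
  check_event_index(k)
  params$lambda * params$alpha^(-k + 1)
}

#' Expected strain increment before the k-th microfailure
#'
#' \eqn{E(\Delta\varepsilon_k) = 1/\lambda_k = \alpha^{k-1}/\lambda},
#' strictly decreasing in k: the process is New-Better-than-Used-in-
#' Expectation (NBUE), with expected quiet intervals shrinking as damage
#' accumulates.
#'
#' @inheritParams event_rate
#' @return Expected increment(s), strain units.
#' @export
expected_increment <- function(k, params) {
  params <- as_coxplosive_params(params)
  check_event_index(k)
  params$alpha^(k - 1) / params$lambda
}

check_event_index <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 1) ||
      any(k != floor(k)))
    stop("event index 'k' must be integer >= 1", call. = FALSE)
  invisible(k)
}

#' Expected total strain accumulated over the explosive event sequence
#'
#' The geometric series of expected increments converges for
#' `0 < alpha < 1`:
#' \deqn{\mu_\infty = \sum_{k \ge 1} \alpha^{k-1}/\lambda
#'       = \frac{1}{(1-\alpha)\lambda}.}
#' This is the expected strain at which the microfailure avalanche
#' completes, i.e. the model's expectation of the strain at macroscopic
#' fracture.
#'
#' @inheritParams event_rate
#' @return Expected total strain \eqn{\mu_\infty}.
#' @export
mu_infinity <- function(params) {
  params <- as_coxplosive_params(params)
  1 / ((1 - params$alpha) * params$lambda)
}

#' Expected strain accumulated between two microfailure indices
#'
#' Expectation of the strain between microfailure `i` and microfailure `j`
#' (the sum of increments k = i+1, ..., j). Under the model's indexing
#' convention, \eqn{E(\Delta\varepsilon_k) = \alpha^{k-1}/\lambda}, the sum
#' telescopes to
#' \deqn{\mu_{i,j} = \frac{\alpha^i - \alpha^j}{(1-\alpha)\lambda},}
#' which is additive (\eqn{\mu_{i,j} + \mu_{j,l} = \mu_{i,l}}) and
#' satisfies \eqn{\mu_{0,\infty} = \mu_\infty}. `form = "literal"` selects
#' an alternative published variant with \eqn{\alpha^{j+1}} in place of
#' \eqn{\alpha^j}; that variant is neither additive nor consistent with
#' \eqn{\mu_\infty} and is provided only for comparison.
#'
#' @param i lower index, integer >= 0 (vectorized).
#' @param j upper index, integer > i; `Inf` allowed.
#' @inheritParams event_rate
#' @param form `"consistent"` (default) or `"literal"` (see Details).
#' @return Expected strain \eqn{\mu_{i,j}}.
#' @examples
#' p <- coxplosive_params(0.5, 2)
#' mu_segment(0, 2, p)        # E(eps_2) = 0.5 + 0.25
#' mu_segment(0, Inf, p)      # equals mu_infinity(p)
#' @export
mu_segment <- function(i, j, params, form = c("consistent", "literal")) {
  params <- as_coxplosive_params(params)
  form <- match.arg(form)
  if (!is.numeric(i) || !is.numeric(j) || any(!is.finite(i)) ||
      any(i < 0) || any(i != floor(i)))
    stop("'i' must be integer >= 0", call. = FALSE)
  if (any(is.finite(j) & j != floor(j)) || any(j < 0))
    stop("'j' must be integer > i (Inf allowed)", call. = FALSE)
  if (any(i >= j))
    stop("'i' must be strictly less than 'j'", call. = FALSE)
  a <- params$alpha
  upper <- if (form == "literal") ifelse(is.infinite(j), 0, a^(j + 1))
           else ifelse(is.infinite(j), 0, a^j)
  (a^i - upper) / ((1 - a) * params$lambda)
}

#' Deterioration rate of the microfailure process
#'
#' The per-event logarithmic growth of the hazard rate,
#' \eqn{\beta = -\ln(\lambda_k / \lambda_{k+1}) = -\ln \alpha > 0},
#' constant in k for the geometric rate law: the model describes constant
#' deterioration. Larger beta means faster embrittlement per microfailure.
#'
#' @inheritParams event_rate
#' @return The deterioration rate \eqn{\beta}, dimensionless.
#' @export
deterioration_rate <- function(params) {
  params <- as_coxplosive_params(params)
  params$beta
}

#' Simulate one realization of the explosive microfailure process
#'
#' Draws strain increments sequentially,
#' \eqn{\Delta\varepsilon_k \sim \mathrm{Exp}(\lambda_k)} with
#' \eqn{\lambda_k = \lambda\alpha^{-k+1}}, and accumulates them. The
#' realization is truncated at `max_events` events or as soon as a drawn
#' increment falls below `min_increment` (the numerical representation of
#' the explosion: increments shrink geometrically, so past some index they
#' are unresolvable). The final cumulative strain approximates the random
#' total strain \eqn{\varepsilon_\infty} whose expectation is
#' [mu_infinity()].
#'
#' @inheritParams event_rate
#' @param max_events truncation on the number of events (>= 1).
#' @param min_increment stop as soon as a drawn increment is smaller than
#'   this (strain units, >= 0; 0 disables the rule).
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return An object of class `"coxplosive_sim"`: list with `increments`,
#'   `cum_strains` (strictly increasing), `params`, `seed`, and
#'   `stop_reason` (`"max_events"` or `"increment_underflow"`).
#' @examples
#' s <- simulate_coxplosive(coxplosive_params(0.9, 50), seed = 1)
#' s$stop_reason
#' tail(s$cum_strains, 1)   # one realization of the total strain
#' @export
simulate_coxplosive <- function(params, max_events = 2000L,
                                min_increment = 1e-12, seed = NULL) {
  params <- as_coxplosive_params(params)
  stopifnot(length(max_events) == 1L, max_events >= 1,
            length(min_increment) == 1L, min_increment >= 0)
  max_events <- as.integer(max_events)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  # one exponential per candidate event; rate grows geometrically, so the
  # draw is vectorized over the whole candidate block and truncated after
  rates <- params$lambda * params$alpha^(-(seq_len(max_events)) + 1)
  incr <- rexp(max_events, rate = 1) / rates
  stop_reason <- "max_events"
  if (min_increment > 0) {
    small <- which(incr < min_increment)
    if (length(small)) {
      n <- small[1L]          # the underflowing draw is kept as the last event
      incr <- incr[seq_len(n)]
      stop_reason <- "increment_underflow"
    }
  }
  cum <- cumsum(incr)
  # geometric shrinkage eventually drops increments below the resolution of
  # the accumulated strain; truncate so cum_strains stays strictly increasing
  flat <- which(diff(cum) <= 0)
  if (length(flat)) {
    keep <- seq_len(flat[1L])
    incr <- incr[keep]
    cum <- cum[keep]
    stop_reason <- "increment_underflow"
  }
  structure(list(increments = incr,
                 cum_strains = cum,
                 params = params,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 stop_reason = stop_reason),
            class = "coxplosive_sim")
}

#' @export
print.coxplosive_sim <- function(x, ...) {
  n <- length(x$increments)
  cat(sprintf("Coxplosive realization: %d events, total strain %.6g (%s)\n",
              n, x$cum_strains[n], x$stop_reason))
  cat(sprintf("  alpha = %.4g, lambda = %.4g, E(total) = %.6g\n",
              x$params$alpha, x$params$lambda, mu_infinity(x$params)))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Cumulative event-count curve N(eps)
#'
#' Number of events detected up to each strain on a grid:
#' \eqn{N(\varepsilon)} = number of event strains \eqn{\le \varepsilon}
#' (closed at the grid point). This is the nondecreasing step curve whose
#' vertical asymptote marks the microfailure avalanche.
#'
#' @param x event strains: a numeric vector, a `"coxplosive_sim"`, or an
#'   `"ae_events"` table.
#' @param grid strain grid, sorted ascending.
#' @return Integer counts, one per grid point.
#' @examples
#' count_curve(c(0.1, 0.2), grid = c(0.05, 0.15, 0.25))  # 0 1 2
#' @export
count_curve <- function(x, grid) {
  strains <- event_strains(x)
  if (!is.numeric(grid) || is.unsorted(grid, strictly = FALSE))
    stop("'grid' must be a numeric vector sorted ascending", call. = FALSE)
  findInterval(grid, sort(strains), left.open = FALSE)
}

event_strains <- function(x) {
  if (inherits(x, "coxplosive_sim")) return(x$cum_strains)
  if (inherits(x, "ae_events")) return(x$strain)
  if (is.numeric(x)) return(x)
  stop("cannot extract event strains from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
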