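#' Choose the lower energy cut-off for the Pareto tail
#'
#' The minimum energy separates genuine microfailure signals from residual
#' and friction-related ones; no universal numeric value exists, so it is
#' configuration. The default takes a low quantile of the observed
#' energies (type-7 quantile, the R default); alternatively a fixed user
#' value is passed through.
#'
#' @param energy positive energies (nonempty).
#' @param method `"quantile"` (default) or `"fixed"`.
#' @param q quantile level for `method = "quantile"` (default 0.05).
#' @param value threshold for `method = "fixed"`.
#' @return The threshold \eqn{E_m > 0}.
#' @export
select_threshold <- function(energy, method = c("quantile", "fixed"),
                             q = 0.05, value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(value), length(value) == 1L, value > 0)
    return(value)
  }
  if (!length(energy)) stop("'energy' must be nonempty", call. = FALSE)
  stopifnot(q >= 0, q <= 1)
  unname(stats::quantile(energy, probs = q, names = FALSE, type = 7))
}

#' Fit a Pareto distribution to AE event energies
#'
#' AE event energies above a minimum threshold follow a Pareto law,
#' \deqn{P(E' \le E) = 1 - (E_m/E)^\nu, \quad E \ge E_m,}
#' with tail exponent \eqn{\nu}. The default estimator is the maximum
#' likelihood (Hill) closed form over the energies strictly above the
#' threshold,
#' \deqn{\hat\nu = n_{\mathrm{tail}} \Big/ \sum_i \ln(E_i/E_m),}
#' which is invariant under a common rescaling of energies and threshold.
#' A least-squares fit of the empirical log-survival curve is available
#' for comparison with spreadsheet-style distribution fitting.
#'
#' @param energy positive energies (an [ae_events()] table is accepted).
#' @param e_m lower cut-off; `NULL` (default) calls [select_threshold()]
#'   with its defaults. Energies `<= e_m` are excluded as residual or
#'   friction-related.
#' @param method `"mle"` (Hill, default) or `"lsq"` (log-survival
#'   regression).
#' @return An object of class `"pareto_fit"`: list with `nu`, `e_m`,
#'   `n_tail`, `method`, `tail` (the energies used). `nu <= 1` is legal
#'   output (infinite-mean regime) and is flagged by `summary()`.
#' @examples
#' set.seed(1)
#' e <- rpareto(500, nu = 1.6, e_m = 1)
#' fit_pareto(e, e_m = 1)
#' @export
fit_pareto <- function(energy, e_m = NULL, method = c("mle", "lsq")) {
  method <- match.arg(method)
  if (inherits(energy, "ae_events")) energy <- energy$energy
  energy <- as.numeric(energy)
  if (!length(energy)) stop("'energy' must be nonempty", call. = FALSE)
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energies must be finite and > 0", call. = FALSE)
  if (is.null(e_m)) e_m <- select_threshold(energy)
  stopifnot(e_m > 0)
  tail_e <- energy[energy > e_m]
  n_tail <- length(tail_e)
  if (n_tail < 2L)
    stop("fewer than 2 energies above the threshold e_m = ", format(e_m),
         "; cannot estimate the tail exponent", call. = FALSE)
  logs <- log(tail_e / e_m)
  if (sum(logs) <= 0)
    stop("all tail energies coincide with the threshold; ",
         "tail exponent estimator diverges", call. = FALSE)
  nu <- if (method == "mle") {
    n_tail / sum(logs)
  } else {
    # empirical survival at the sorted tail energies, midpoint plotting rule
    se <- sort(tail_e)
    surv <- (n_tail - seq_len(n_tail) + 0.5) / n_tail
    -unname(coef(stats::lm(log(surv) ~ log(se / e_m)))[2L])
  }
  structure(list(nu = nu, e_m = e_m, n_tail = n_tail, method = method,
                 tail = tail_e),
            class = "pareto_fit")
}

#' @export
print.pareto_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Pareto fit of AE energies (%s): nu = %s, E_m = %s, n_tail = %d\n",
              x$method, format(x$nu, digits = digits),
              format(x$e_m, digits = digits), x$n_tail))
  invisible(x)
}

#' @export
coef.pareto_fit <- function(object, ...) {
  c(nu = object$nu, e_m = object$e_m)
}

#' @export
summary.pareto_fit <- function(object, ...) {
  se <- object$nu / sqrt(object$n_tail)  # asymptotic MLE standard error
  out <- c(object[c("nu", "e_m", "n_tail", "method")],
           list(se_nu = se, finite_mean = object$nu > 1))
  class(out) <- "summary.pareto_fit"
  out
}

#' @export
print.summary.pareto_fit <- function(x, digits = 4, ...) {
  cat("Pareto tail of AE event energies\n")
  cat(sprintf("  nu      %s  (se %s, %s)\n", format(x$nu, digits = digits),
              format(x$se_nu, digits = digits), x$method))
  cat(sprintf("  E_m     %s\n", format(x$e_m, digits = digits)))
  cat(sprintf("  n_tail  %d\n", x$n_tail))
  if (!x$finite_mean)
    cat("  note: nu <= 1, the fitted energy distribution has infinite mean\n")
  invisible(x)
}

#' Log-survival plot of the fitted energy tail
#'
#' Empirical survival fraction of the tail energies on log-log axes with
#' the fitted power law overlaid; a straight-line pattern supports the
#' Pareto model.
#'
#' @param x a `"pareto_fit"`.
#' @param ... further arguments to `plot()`.
#' @export
plot.pareto_fit <- function(x, ...) {
  se <- sort(x$tail)
  surv <- (x$n_tail - seq_len(x$n_tail) + 0.5) / x$n_tail
  plot(se, surv, log = "xy", xlab = "energy E",
       ylab = "P(energy > E)", ...)
  graphics::lines(se, (x$e_m / se)^x$nu, col = "red")
  invisible(x)
}

#' Draw Pareto-distributed AE energies
#'
#' Inverse-CDF sampling from \eqn{P(E' \le E) = 1 - (E_m/E)^\nu}.
#'
#' @param n sample size.
#' @param nu tail exponent > 0.
#' @param e_m minimum energy > 0.
#' @return `n` draws, all `> e_m` almost surely.
#' @export
rpareto <- function(n, nu, e_m = 1) {
  stopifnot(nu > 0, e_m > 0)
  e_m * stats::runif(n)^(-1 / nu)
}
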