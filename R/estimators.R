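#' Branching times of a crown clade
#'
#' Container for the node ages of an ultrametric (crown) clade: \code{n}
#' tips have \code{n - 1} branching ages, measured backwards from the
#' present, the oldest being the crown age \code{T}.  Input order is
#' irrelevant; ages are sorted internally.
#'
#' @param ages Numeric vector of node ages (Myr before present), all
#'   positive; the maximum is the crown age.
#' @return An object of class \code{"branching_times"}: list with
#'   \code{ages} (sorted descending), \code{n} and \code{T}.
#' @seealso [as_branching_times()] to extract them from a tree.
#' @export
branching_times <- function(ages) {
  if (!is.numeric(ages) || length(ages) < 1L)
    stop("'ages' must be a non-empty numeric vector")
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("branching ages must be finite and positive")
  ages <- sort(as.numeric(ages), decreasing = TRUE)
  structure(list(ages = ages, n = length(ages) + 1L, T = ages[1L]),
            class = "branching_times")
}

#' @rdname branching_times
#' @param tree An ultrametric \code{"phylo"} object (a \code{root.edge}, if
#'   any, is ignored: ages are crown-based).
#' @export
as_branching_times <- function(tree) {
  tree <- check_tree(tree)
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  branching_times(as.numeric(ape::branching.times(tree)))
}

rate_estimate <- function(lambda_hat, mu_hat = NA_real_, method,
                          log_likelihood = NA_real_, ...) {
  structure(list(lambda_hat = lambda_hat, mu_hat = mu_hat, method = method,
                 log_likelihood = log_likelihood, ...),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Speciation rate estimate (%s)\n", x$method))
  cat(sprintf("  lambda_hat = %.6g per lineage per Myr\n", x$lambda_hat))
  if (!is.na(x$mu_hat))
    cat(sprintf("  mu_hat     = %.6g per lineage per Myr\n", x$mu_hat))
  if (!is.na(x$log_likelihood))
    cat(sprintf("  log-likelihood = %.6g\n", x$log_likelihood))
  invisible(x)
}

#' Richness-versus-age speciation rate
#'
#' The pure-birth expectation from a single ancestor gives
#' \eqn{\hat\lambda = \ln(n) / t} for \code{n} extant species in a clade of
#' age \code{t}.  Because every extinct or reabsorbed lineage is invisible
#' to it, this is a minimum-bound style estimate of the true speciation
#' rate.  Applied to the Lake Victoria cichlid flock (~450 species in
#' ~15,000 years) it gives ~400 events per lineage per Myr to one
#' significant figure.
#'
#' @param n Number of extant species (>= 1).
#' @param t Clade age in Myr (> 0).
#' @return A \code{"rate_estimate"} with method \code{"richness_age"}.
#' @examples
#' richness_age_rate(450, 0.015)  # ~407, i.e. 400 to 1 s.f.
#' @export
richness_age_rate <- function(n, t) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single number >= 1")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive number (Myr)")
  rate_estimate(log(n) / t, method = "richness_age")
}

#' Speciation rate implied by a waiting time between events
#'
#' Converts a waiting time expressed in generations into a per-lineage rate
#' per million years: \eqn{10^6 / (\mathrm{generations} \times
#' \mathrm{years\ per\ generation})}.  Waiting times of 5,000--200,000
#' generations at one year per generation give 200 down to 5 events per
#' lineage per Myr (a published lower figure of 2 corresponds to a waiting
#' time above 200,000 generations).
#'
#' @param waiting_generations Generations between successive speciation
#'   events (> 0).
#' @param generation_time_years Generation time in years (> 0).
#' @return A \code{"rate_estimate"} with method \code{"waiting_time"}.
#' @examples
#' waiting_time_to_rate(5000, 1)  # 200
#' @export
waiting_time_to_rate <- function(waiting_generations, generation_time_years) {
  for (v in list(waiting_generations, generation_time_years))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("both arguments must be single positive numbers")
  rate_estimate(1e6 / (waiting_generations * generation_time_years),
                method = "waiting_time")
}

# total lineage-time exposure of a crown clade: sum over intervals of
# (number of lineages) x (interval duration), from 2 lineages at the crown
# to n at the present
yule_exposure <- function(bt) {
  x <- bt$ages
  2 * x[1L] + sum(x[-1L])
}

#' Yule (pure-birth) maximum-likelihood speciation rate
#'
#' Closed-form MLE for a crown clade:
#' \eqn{\hat\lambda = (n - 2) / E} where \eqn{E = \sum_i i\, g_i} is the
#' total lineage-time exposure from the crown (2 lineages) to the present
#' (\eqn{g_i} = duration with \eqn{i} lineages, including the final
#' interval with \eqn{n}).  \eqn{n - 2} is the number of observable
#' branching events after the crown split.  The reported log-likelihood is
#' the birth--death likelihood at \eqn{(\hat\lambda, 0)}, so it is directly
#' comparable with [fit_birth_death()].
#'
#' @param bt A [branching_times()] object with \code{n >= 3}.
#' @return A \code{"rate_estimate"} with method \code{"yule_ml"}.
#' @examples
#' fit_yule(branching_times(c(2, 1)))  # exposure 5, lambda_hat 0.2
#' @export
fit_yule <- function(bt) {
  stopifnot(inherits(bt, "branching_times"))
  if (bt$n < 3L)
    stop("Yule MLE needs n >= 3 (no observable events otherwise)")
  E <- yule_exposure(bt)
  lambda <- (bt$n - 2L) / E
  rate_estimate(lambda, mu_hat = NA_real_, method = "yule_ml",
                log_likelihood = bd_loglik(lambda, 0, bt))
}

#' Reconstructed-process birth--death log-likelihood
#'
#' The log-likelihood of the branching times of a reconstructed
#' (extant-only) ultrametric tree under a constant-rate birth--death
#' process, conditioned on the survival of both crown lineages: with
#' \eqn{r = \lambda - \mu}, \eqn{a = \mu/\lambda} and ages \eqn{x_2 \ge
#' x_3 \ge \ldots \ge x_n} (\eqn{x_2} the crown age),
#' \deqn{\log L = \log (n-1)! + (n-2)\log r + r \sum_{i=3}^{n} x_i
#'   + n \log(1 - a) - 2 \sum_{i=2}^{n} \log(e^{r x_i} - a).}
#' Defined for \eqn{0 \le \mu < \lambda} (the supercritical regime the
#' conditioning assumes); returns \code{-Inf} outside it.
#'
#' @param lambda Speciation rate per lineage per Myr.
#' @param mu Extinction rate per lineage per Myr.
#' @param bt A [branching_times()] object.
#' @return The log-likelihood, a single number.
#' @export
bd_loglik <- function(lambda, mu, bt) {
  stopifnot(inherits(bt, "branching_times"))
  if (!is.finite(lambda) || !is.finite(mu) || lambda <= 0 || mu < 0 ||
      mu >= lambda)
    return(-Inf)
  x <- bt$ages
  n <- bt$n
  r <- lambda - mu
  a <- mu / lambda
  # log(exp(r x) - a) = r x + log1p(-a exp(-r x)), stable for large r x
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(x[-1L]) +
    n * log1p(-a) - 2 * sum(r * x + log1p(-a * exp(-r * x)))
}

#' Birth--death maximum-likelihood fit to branching times
#'
#' Numerically maximizes [bd_loglik()] over \eqn{(\lambda, \mu)} via the
#' \eqn{(r, a) = (\lambda - \mu, \mu/\lambda)} parameterization, with
#' bounded quasi-Newton (L-BFGS-B) from two starts: the Yule MLE with
#' \eqn{\mu = 0}, and \eqn{\mu = \lambda/2}.  Ages are rescaled to unit
#' crown age internally, so estimates are exactly equivariant under a
#' change of time unit.  Convergence tolerance is \code{1e-8} on the
#' log-likelihood; non-convergence of all starts is an error.
#'
#' @param bt A [branching_times()] object; \code{n >= 4} recommended.
#' @return A \code{"rate_estimate"} with method \code{"bd_ml"}, fields
#'   \code{lambda_hat}, \code{mu_hat}, \code{log_likelihood} and
#'   \code{convergence} (the optimizer status of the best start).
#' @examples
#' bt <- branching_times(c(8, 5, 3, 2, 1, 0.5))
#' fit_birth_death(bt)
#' @export
fit_birth_death <- function(bt) {
  stopifnot(inherits(bt, "branching_times"))
  if (bt$n < 3L) stop("birth-death fit needs n >= 3")
  scale <- bt$T
  bts <- branching_times(bt$ages / scale)
  nll <- function(p) {
    r <- p[1L]; a <- p[2L]
    lambda <- r / (1 - a)
    -bd_loglik(lambda, a * lambda, bts)
  }
  r0 <- fit_yule_lambda(bts)
  starts <- list(c(r0, 1e-4), c(r0 / 2, 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = c(1e-9, 0), upper = c(Inf, 1 - 1e-9),
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0L) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("birth-death optimizer failed to converge from all starts")
  r <- best$par[1L]; a <- best$par[2L]
  lambda <- r / (1 - a) / scale
  mu <- a * r / (1 - a) / scale
  rate_estimate(lambda, mu_hat = mu, method = "bd_ml",
                log_likelihood = bd_loglik(lambda, mu, bt),
                convergence = best$convergence)
}

fit_yule_lambda <- function(bt) (bt$n - 2L) / yule_exposure(bt)
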