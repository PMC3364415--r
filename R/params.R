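#' Parameters of the hierarchical ephemeral speciation model
#'
#' The model has three rates, all per incipient lineage per million years
#' (Myr): incipient lineages arise within their species by branching at rate
#' \code{lambda_i}, are lost (extinction or reabsorption into the parental
#' species) at rate \code{mu_i}, and are promoted to new full species at rate
#' \code{lambda_f}.
#'
#' The defaults place the incipient branching rate 30--40 times above the
#' full-species formation rate (\code{lambda_i / lambda_f} ~ 33), the regime
#' reported for avian subspeciation relative to speciation, with moderate
#' incipient turnover (\code{mu_i = 0.5}).
#'
#' @param lambda_i Incipient speciation (branching) rate, per lineage per Myr.
#' @param mu_i Incipient loss rate (extinction or reabsorption), per lineage
#'   per Myr.
#' @param lambda_f Full-species formation (conversion) rate, per lineage per
#'   Myr.
#' @param t_max Simulation horizon in Myr.
#' @param max_lineages Hard cap on concurrently alive incipient lineages; a
#'   run that exceeds it stops with a classed warning and is flagged
#'   \code{capped = TRUE}, never silently truncated.
#' @param seed Optional integer RNG seed; \code{NULL} continues the current
#'   RNG stream.
#' @return An object of class \code{"esm_params"}.
#' @seealso [simulate_esm()], [bd_params()]
#' @examples
#' esm_params(lambda_i = 1, mu_i = 0.5, lambda_f = 0.03, t_max = 10)
#' @export
esm_params <- function(lambda_i = 1.0, mu_i = 0.5, lambda_f = 0.03,
                       t_max = 10, max_lineages = 50000L, seed = NULL) {
  check_rate(lambda_i, "lambda_i")
  check_rate(mu_i, "mu_i")
  check_rate(lambda_f, "lambda_f")
  check_horizon(t_max, max_lineages, seed)
  structure(
    list(lambda_i = as.numeric(lambda_i), mu_i = as.numeric(mu_i),
         lambda_f = as.numeric(lambda_f), t_max = as.numeric(t_max),
         max_lineages = as.integer(max_lineages),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "esm_params")
}

#' Parameters of the constant-rate birth--death baseline
#'
#' The "high turnover" contrast model: every lineage is its own species,
#' speciating at rate \code{lambda} and going extinct at rate \code{mu}.
#'
#' @param lambda Speciation rate per lineage per Myr.
#' @param mu Extinction rate per lineage per Myr.
#' @inheritParams esm_params
#' @return An object of class \code{"bd_params"}.
#' @seealso [simulate_bd()]
#' @export
bd_params <- function(lambda = 1.0, mu = 0.5, t_max = 10,
                      max_lineages = 50000L, seed = NULL) {
  check_rate(lambda, "lambda")
  check_rate(mu, "mu")
  check_horizon(t_max, max_lineages, seed)
  structure(
    list(lambda = as.numeric(lambda), mu = as.numeric(mu),
         t_max = as.numeric(t_max), max_lineages = as.integer(max_lineages),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "bd_params")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single finite non-negative number", name),
         call. = FALSE)
  invisible(x)
}

check_horizon <- function(t_max, max_lineages, seed) {
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0)
    stop("'t_max' must be a single finite positive number (Myr)",
         call. = FALSE)
  if (!is.numeric(max_lineages) || length(max_lineages) != 1L ||
      !is.finite(max_lineages) || max_lineages < 1)
    stop("'max_lineages' must be >= 1", call. = FALSE)
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)))
    stop("'seed' must be NULL or a single integer", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.esm_params <- function(x, ...) {
  cat("Ephemeral speciation model parameters (rates per lineage per Myr)\n")
  cat(sprintf("  lambda_i = %g, mu_i = %g, lambda_f = %g\n",
              x$lambda_i, x$mu_i, x$lambda_f))
  cat(sprintf("  t_max = %g Myr, max_lineages = %d, seed = %s\n",
              x$t_max, x$max_lineages,
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' @export
print.bd_params <- function(x, ...) {
  cat("Birth-death baseline parameters (rates per lineage per Myr)\n")
  cat(sprintf("  lambda = %g, mu = %g\n", x$lambda, x$mu))
  cat(sprintf("  t_max = %g Myr, max_lineages = %d, seed = %s\n",
              x$t_max, x$max_lineages,
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}
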