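#' Simulate the constant-rate birth--death baseline
#'
#' The "high turnover" contrast model: a flat Gillespie birth--death process
#' started from one lineage, in which every lineage is its own species
#' (births found new species at the moment of branching; there are no
#' conversion events).  The result uses the same \code{"esm_sim"} container
#' as [simulate_esm()], so every summary applies unchanged.
#'
#' @param params A [bd_params()] object.
#' @return An object of class \code{"esm_sim"} with \code{model = "bd"}.
#' @seealso [expected_diversity()], [simulate_esm()]
#' @examples
#' res <- simulate_bd(bd_params(1, 0, t_max = 2, seed = 1))
#' res$n_alive_final
#' @export
simulate_bd <- function(params) {
  if (!inherits(params, "bd_params"))
    stop("'params' must be a bd_params object")
  out <- .sim_engine(params$lambda, params$mu, 0, params$t_max,
                     params$max_lineages, params$seed,
                     branch_new_species = TRUE)
  out$model <- "bd"
  out$params <- params
  class(out) <- "esm_sim"
  out
}

#' Expected lineage count under constant-rate birth--death
#'
#' \eqn{E[N(t)] = n_0 e^{(\lambda - \mu) t}}: diversity grows (or decays)
#' exponentially at the net rate, so deep-time lineage accumulation is
#' log-linear under this model.
#'
#' @param lambda Speciation rate per lineage per Myr.
#' @param mu Extinction rate per lineage per Myr.
#' @param t Elapsed time in Myr.
#' @param n0 Initial number of lineages.
#' @return The expected number of lineages at time \code{t}.
#' @examples
#' expected_diversity(1, 0, 2)      # e^2
#' expected_diversity(0.3, 0.1, 10) # depends only on lambda - mu
#' @export
expected_diversity <- function(lambda, mu, t, n0 = 1) {
  check_rate(lambda, "lambda")
  check_rate(mu, "mu")
  if (!is.numeric(t) || any(t < 0) || any(!is.finite(t)))
    stop("'t' must be non-negative and finite")
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1)
    stop("'n0' must be >= 1")
  n0 * exp((lambda - mu) * t)
}
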