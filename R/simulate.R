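#' Simulate the hierarchical ephemeral speciation model
#'
#' Exact event-driven (Gillespie) simulation.  The state starts at time 0
#' with one full species containing one incipient lineage.  While lineages
#' remain and the horizon has not been reached, the waiting time to the next
#' event is exponential with rate \eqn{n (\lambda_i + \mu_i + \lambda_f)}
#' for \eqn{n} living lineages; a living lineage is chosen uniformly and the
#' event kind with probabilities proportional to
#' \eqn{(\lambda_i, \mu_i, \lambda_f)}:
#' \describe{
#'   \item{branch}{a new incipient lineage is added to the same species;}
#'   \item{loss}{the lineage dies -- labelled \code{reabsorption} when its
#'     species retains at least one other living lineage, and
#'     \code{species_extinction} when it was the species' last, so whole
#'     species go extinct only when all their incipient forms are lost;}
#'   \item{conversion}{the lineage founds a fresh full species containing
#'     only itself; incipient descendants it spawned earlier stay in the old
#'     species.  A conversion drawn for a lineage that is its species' only
#'     member changes nothing and is logged as a no-op
#'     (\code{new_species_id == species_id}).}
#' }
#'
#' @param params An [esm_params()] object.
#' @return An object of class \code{"esm_sim"}: a list with data frames
#'   \code{lineages} (the full genealogy in budding form), \code{species}
#'   (origin, parentage, extinction and final membership of every species),
#'   \code{events} (the time-ordered log with columns \code{seq},
#'   \code{time}, \code{kind}, \code{lineage_id}, \code{species_id},
#'   \code{new_species_id}, \code{label}) and \code{membership}
#'   (lineage-species residency intervals), plus \code{n_alive_final},
#'   \code{surviving}, \code{n_species_extant}, \code{capped},
#'   \code{horizon}, \code{model} and the \code{params}.
#' @seealso [condition_on_survival()], [collapse_to_species_tree()],
#'   [species_membership_counts()], [simulate_bd()]
#' @examples
#' res <- simulate_esm(esm_params(1, 0.5, 0.05, t_max = 5, seed = 1))
#' res$n_species_extant
#' @export
simulate_esm <- function(params) {
  if (!inherits(params, "esm_params"))
    stop("'params' must be an esm_params object")
  out <- .sim_engine(params$lambda_i, params$mu_i, params$lambda_f,
                     params$t_max, params$max_lineages, params$seed,
                     branch_new_species = FALSE)
  out$model <- "ephemeral"
  out$params <- params
  class(out) <- "esm_sim"
  out
}

#' Rejection-sample a simulation conditioned on survival
#'
#' Repeats [simulate_esm()] (or [simulate_bd()] for \code{"bd_params"})
#' until at least one incipient lineage is alive at the horizon.  Clades
#' observed today are exactly such survivors, and survivorship is the
#' mechanism behind the apparent early burst of speciation in reconstructed
#' trees.
#'
#' If \code{params$seed} is set, the RNG is seeded once and the rejection
#' attempts consume one continuous stream, so the result is reproducible.
#'
#' @param params An [esm_params()] or [bd_params()] object.
#' @param max_tries Maximum number of attempts before giving up.
#' @return The first surviving \code{"esm_sim"} result, with the number of
#'   attempts in its \code{attempts} element.
#' @examples
#' res <- condition_on_survival(esm_params(1, 0.8, 0.05, t_max = 5, seed = 1))
#' res$surviving
#' @export
condition_on_survival <- function(params, max_tries = 1000L) {
  if (!is.numeric(max_tries) || length(max_tries) != 1L || max_tries < 1)
    stop("'max_tries' must be >= 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  p$seed <- NULL
  simfun <- if (inherits(params, "bd_params")) simulate_bd else simulate_esm
  for (i in seq_len(max_tries)) {
    res <- simfun(p)
    if (res$surviving) {
      res$attempts <- i
      res$params <- params
      return(res)
    }
  }
  stop(sprintf(
    "no surviving replicate in %d attempts; survival probability too low for these parameters",
    as.integer(max_tries)))
}

#' @export
print.esm_sim <- function(x, ...) {
  cat(sprintf("%s model simulation (horizon %g Myr%s)\n",
              if (x$model == "bd") "Birth-death" else "Ephemeral speciation",
              x$horizon, if (x$capped) ", capped" else ""))
  cat(sprintf("  %d lineages total, %d alive at horizon; %d species, %d extant\n",
              nrow(x$lineages), x$n_alive_final,
              nrow(x$species), x$n_species_extant))
  cat(sprintf("  %d events (%d branch, %d loss, %d conversion)\n",
              nrow(x$events), sum(x$events$kind == "branch"),
              sum(x$events$kind == "loss"),
              sum(x$events$kind == "conversion")))
  invisible(x)
}
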