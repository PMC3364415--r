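#' Living incipient lineages per species at a given time
#'
#' Replays the event log from time 0 to \code{at_time} (events at exactly
#' \code{at_time} included) and returns the number of living incipient
#' lineages in each species; species with zero members are omitted.  This is
#' deliberately computed from the log alone, so it doubles as an integrity
#' check on the simulator's state tables.
#'
#' @param result An \code{"esm_sim"} object.
#' @param at_time Time in Myr, within \code{[0, result$horizon]}.
#' @return A named integer vector: species id -> living lineage count.
#' @examples
#' res <- simulate_esm(esm_params(1, 0.5, 0.05, t_max = 5, seed = 1))
#' species_membership_counts(res, at_time = 5)
#' @export
species_membership_counts <- function(result, at_time) {
  stopifnot(inherits(result, "esm_sim"))
  if (!is.numeric(at_time) || length(at_time) != 1L ||
      at_time < 0 || at_time > result$horizon)
    stop(sprintf("'at_time' must be in [0, %g]", result$horizon))
  counts <- replay_counts(result$events, at_time)
  counts[counts > 0L]
}

# replay branch/loss/conversion increments up to and including 'at_time';
# returns the full (possibly zero) per-species count vector
replay_counts <- function(events, at_time) {
  n_sp <- max(1L, events$species_id, events$new_species_id, na.rm = TRUE)
  counts <- integer(n_sp)
  counts[1L] <- 1L  # root species starts with one lineage
  keep <- events$time <= at_time
  if (any(keep)) {
    ev <- events[keep, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      k <- ev$kind[i]
      if (k == "branch") {
        s <- if (is.na(ev$new_species_id[i])) ev$species_id[i]
             else ev$new_species_id[i]
        counts[s] <- counts[s] + 1L
      } else if (k == "loss") {
        counts[ev$species_id[i]] <- counts[ev$species_id[i]] - 1L
      } else {  # conversion; no-op when new_species_id == species_id
        s_old <- ev$species_id[i]; s_new <- ev$new_species_id[i]
        if (s_new != s_old) {
          counts[s_old] <- counts[s_old] - 1L
          counts[s_new] <- counts[s_new] + 1L
        }
      }
    }
  }
  names(counts) <- seq_along(counts)
  counts
}

# running total lineage count after each event (branch +1, loss -1,
# conversion 0); used by tests and the log-integrity check
running_lineage_count <- function(events) {
  step <- ifelse(events$kind == "branch", 1L,
                 ifelse(events$kind == "loss", -1L, 0L))
  1L + cumsum(step)
}

#' Check internal consistency of a simulation result
#'
#' Verifies that the running lineage count implied by the event log matches
#' \code{n_alive_final}, never goes negative, and that the species table
#' agrees with a full replay of the log.  Stops on the first violation.
#'
#' @param result An \code{"esm_sim"} object.
#' @return \code{TRUE}, invisibly.
#' @export
validate_sim <- function(result) {
  stopifnot(inherits(result, "esm_sim"))
  ev <- result$events
  if (nrow(ev) > 0L) {
    run <- running_lineage_count(ev)
    if (any(run < 0L)) stop("running lineage count went negative")
    if (run[length(run)] != result$n_alive_final)
      stop("event log does not reproduce n_alive_final")
    if (is.unsorted(ev$time)) stop("events not time-ordered")
  } else if (result$n_alive_final != 1L) {
    stop("empty log but n_alive_final != 1")
  }
  counts <- replay_counts(ev, result$horizon)
  tab <- integer(nrow(result$species))
  tab[result$species$species_id] <- result$species$n_incipient
  if (!identical(unname(counts), tab))
    stop("species table disagrees with event-log replay")
  if (result$surviving != (result$n_alive_final >= 1L))
    stop("'surviving' flag inconsistent")
  invisible(TRUE)
}
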