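# Shared Gillespie engine for the hierarchical and the flat (birth-death)
# model.  State is held in preallocated vectors grown geometrically; every
# event is O(1).  In the hierarchical model a branch adds an incipient
# lineage to the branching lineage's species and a conversion moves the
# chosen lineage into a fresh species (its earlier descendants stay behind);
# in the flat model every new lineage founds its own species and the
# conversion channel is off.

EV_BRANCH <- 1L
EV_LOSS <- 2L
EV_CONVERSION <- 3L

LAB_NONE <- 0L
LAB_REABSORPTION <- 1L
LAB_EXTINCTION <- 2L

.sim_engine <- function(lambda_b, mu, lambda_c, t_max, cap, seed,
                        branch_new_species) {
  if (!is.null(seed)) set.seed(seed)

  # lineages
  nl <- 256L
  lin_parent <- rep(NA_integer_, nl); lin_birth <- numeric(nl)
  lin_death <- rep(NA_real_, nl); lin_sp0 <- integer(nl)
  cur_sp <- integer(nl); enter_t <- numeric(nl)
  n_lin <- 1L
  lin_birth[1L] <- 0; lin_sp0[1L] <- 1L; cur_sp[1L] <- 1L; enter_t[1L] <- 0

  # species
  ns <- 64L
  sp_parent <- rep(NA_integer_, ns); sp_founder <- integer(ns)
  sp_t0 <- numeric(ns); sp_tend <- rep(NA_real_, ns); sp_m <- integer(ns)
  n_sp <- 1L
  sp_founder[1L] <- 1L; sp_t0[1L] <- 0; sp_m[1L] <- 1L

  # alive set with O(1) swap-removal
  alive <- integer(nl); alive[1L] <- 1L; n_alive <- 1L
  pos <- integer(nl); pos[1L] <- 1L

  # event log
  ne <- 512L
  ev_t <- numeric(ne); ev_k <- integer(ne); ev_lin <- integer(ne)
  ev_sp <- integer(ne); ev_sp2 <- rep(NA_integer_, ne); ev_lab <- integer(ne)
  n_ev <- 0L

  # membership intervals (lineage x species residency)
  nm <- 512L
  mi_lin <- integer(nm); mi_sp <- integer(nm)
  mi_a <- numeric(nm); mi_b <- numeric(nm)
  n_mi <- 0L

  total <- lambda_b + mu + lambda_c
  t <- 0
  capped <- FALSE

  if (total > 0) repeat {
    if (n_alive == 0L) break
    dt <- stats::rexp(1L, n_alive * total)
    if (t + dt >= t_max) break
    t <- t + dt
    lin <- alive[sample.int(n_alive, 1L)]
    u <- stats::runif(1L) * total

    # ensure room for one more event / lineage / species / interval
    if (n_ev + 1L > ne) {
      ne <- 2L * ne
      length(ev_t) <- ne; length(ev_k) <- ne; length(ev_lin) <- ne
      length(ev_sp) <- ne; length(ev_sp2) <- ne; length(ev_lab) <- ne
    }
    if (n_mi + 1L > nm) {
      nm <- 2L * nm
      length(mi_lin) <- nm; length(mi_sp) <- nm
      length(mi_a) <- nm; length(mi_b) <- nm
    }

    if (u < lambda_b) {                                 # branch
      if (n_lin + 1L > nl) {
        nl <- 2L * nl
        length(lin_parent) <- nl; length(lin_birth) <- nl
        length(lin_death) <- nl; length(lin_sp0) <- nl
        length(cur_sp) <- nl; length(enter_t) <- nl
        length(alive) <- nl; length(pos) <- nl
      }
      id <- n_lin <- n_lin + 1L
      lin_parent[id] <- lin; lin_birth[id] <- t; enter_t[id] <- t
      s <- cur_sp[lin]
      s_new <- NA_integer_
      if (branch_new_species) {
        if (n_sp + 1L > ns) {
          ns <- 2L * ns
          length(sp_parent) <- ns; length(sp_founder) <- ns
          length(sp_t0) <- ns; length(sp_tend) <- ns; length(sp_m) <- ns
        }
        s_new <- n_sp <- n_sp + 1L
        sp_parent[s_new] <- s; sp_founder[s_new] <- id
        sp_t0[s_new] <- t; sp_m[s_new] <- 1L
        cur_sp[id] <- s_new; lin_sp0[id] <- s_new
      } else {
        sp_m[s] <- sp_m[s] + 1L
        cur_sp[id] <- s; lin_sp0[id] <- s
      }
      n_alive <- n_alive + 1L
      alive[n_alive] <- id; pos[id] <- n_alive
      n_ev <- n_ev + 1L
      ev_t[n_ev] <- t; ev_k[n_ev] <- EV_BRANCH; ev_lin[n_ev] <- lin
      ev_sp[n_ev] <- s; ev_sp2[n_ev] <- s_new; ev_lab[n_ev] <- LAB_NONE
      if (n_alive > cap) {
        capped <- TRUE
        warning(capped_growth_condition(n_alive, cap, t))
        break
      }
    } else if (u < lambda_b + mu) {                     # loss
      s <- cur_sp[lin]
      sp_m[s] <- sp_m[s] - 1L
      lin_death[lin] <- t
      k <- pos[lin]                                     # swap-remove
      last <- alive[n_alive]
      alive[k] <- last; pos[last] <- k
      n_alive <- n_alive - 1L
      lab <- if (sp_m[s] == 0L) { sp_tend[s] <- t; LAB_EXTINCTION
             } else LAB_REABSORPTION
      n_mi <- n_mi + 1L
      mi_lin[n_mi] <- lin; mi_sp[n_mi] <- s
      mi_a[n_mi] <- enter_t[lin]; mi_b[n_mi] <- t
      n_ev <- n_ev + 1L
      ev_t[n_ev] <- t; ev_k[n_ev] <- EV_LOSS; ev_lin[n_ev] <- lin
      ev_sp[n_ev] <- s; ev_lab[n_ev] <- lab
    } else {                                            # conversion
      s <- cur_sp[lin]
      if (sp_m[s] >= 2L) {
        if (n_sp + 1L > ns) {
          ns <- 2L * ns
          length(sp_parent) <- ns; length(sp_founder) <- ns
          length(sp_t0) <- ns; length(sp_tend) <- ns; length(sp_m) <- ns
        }
        s_new <- n_sp <- n_sp + 1L
        sp_parent[s_new] <- s; sp_founder[s_new] <- lin
        sp_t0[s_new] <- t; sp_m[s_new] <- 1L
        sp_m[s] <- sp_m[s] - 1L
        n_mi <- n_mi + 1L
        mi_lin[n_mi] <- lin; mi_sp[n_mi] <- s
        mi_a[n_mi] <- enter_t[lin]; mi_b[n_mi] <- t
        cur_sp[lin] <- s_new; enter_t[lin] <- t
      } else {
        # the lineage is its species' only member: promoting it creates
        # nothing new; recorded as a no-op (new_species_id == species_id)
        s_new <- s
      }
      n_ev <- n_ev + 1L
      ev_t[n_ev] <- t; ev_k[n_ev] <- EV_CONVERSION; ev_lin[n_ev] <- lin
      ev_sp[n_ev] <- s; ev_sp2[n_ev] <- s_new; ev_lab[n_ev] <- LAB_NONE
    }
  }

  horizon <- if (capped) t else t_max

  # close residency intervals of lineages alive at the horizon
  if (n_alive > 0L) {
    live <- alive[seq_len(n_alive)]
    idx <- n_mi + seq_along(live)
    need <- n_mi + length(live)
    if (need > nm) {
      nm <- max(2L * nm, need)
      length(mi_lin) <- nm; length(mi_sp) <- nm
      length(mi_a) <- nm; length(mi_b) <- nm
    }
    mi_lin[idx] <- live; mi_sp[idx] <- cur_sp[live]
    mi_a[idx] <- enter_t[live]; mi_b[idx] <- horizon
    n_mi <- need
  }

  li <- seq_len(n_lin); si <- seq_len(n_sp); ei <- seq_len(n_ev)
  mi <- seq_len(n_mi)
  kinds <- c("branch", "loss", "conversion")
  labels <- c(NA_character_, "reabsorption", "species_extinction")

  lineages <- data.frame(
    id = li,
    parent_id = lin_parent[li],
    birth_time = lin_birth[li],
    death_time = lin_death[li],
    species_at_birth = lin_sp0[li],
    species_final = cur_sp[li],
    fate = ifelse(is.na(lin_death[li]), "alive", "lost"))

  species <- data.frame(
    species_id = si,
    parent_species = sp_parent[si],
    founder_lineage = sp_founder[si],
    origin_time = sp_t0[si],
    extinction_time = sp_tend[si],
    n_incipient = sp_m[si],
    extant = sp_m[si] > 0L)

  events <- data.frame(
    seq = ei,
    time = ev_t[ei],
    kind = kinds[ev_k[ei]],
    lineage_id = ev_lin[ei],
    species_id = ev_sp[ei],
    new_species_id = ev_sp2[ei],
    label = labels[ev_lab[ei] + 1L])

  membership <- data.frame(
    lineage_id = mi_lin[mi],
    species_id = mi_sp[mi],
    t_from = mi_a[mi],
    t_to = mi_b[mi])

  list(lineages = lineages, species = species, events = events,
       membership = membership,
       n_alive_final = n_alive,
       surviving = n_alive >= 1L,
       n_species_extant = sum(sp_m[si] > 0L),
       capped = capped,
       horizon = horizon)
}

capped_growth_condition <- function(n_alive, cap, time) {
  structure(
    class = c("ephemsim_capped_growth", "warning", "condition"),
    list(message = sprintf(
           "lineage count %d exceeded max_lineages = %d at t = %.6g; simulation stopped and flagged",
           n_alive, cap, time),
         call = NULL))
}
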