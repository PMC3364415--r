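# Fixtures built in code, plus small independent oracles.

# Minimal esm_sim object from hand-written tables; only the pieces a given
# test touches need to be supplied.
manual_sim <- function(events = NULL, species = NULL, lineages = NULL,
                       membership = NULL, horizon = 10,
                       params = esm_params(t_max = horizon),
                       n_alive_final = NA_integer_, model = "ephemeral") {
  if (!is.null(events)) {
    events$seq <- seq_len(nrow(events))
    if (is.null(events$new_species_id)) events$new_species_id <- NA_integer_
    if (is.null(events$label)) events$label <- NA_character_
  } else {
    events <- data.frame(seq = integer(), time = numeric(),
                         kind = character(), lineage_id = integer(),
                         species_id = integer(),
                         new_species_id = integer(), label = character())
  }
  structure(list(model = model, params = params, lineages = lineages,
                 species = species, events = events,
                 membership = membership,
                 n_alive_final = n_alive_final,
                 surviving = is.na(n_alive_final) || n_alive_final >= 1L,
                 n_species_extant = if (is.null(species)) NA_integer_
                                    else sum(species$extant),
                 capped = FALSE, horizon = horizon),
            class = "esm_sim")
}

# Three-species fixture: conversions at t = 1 and t = 2, founders born
# earlier, everything surviving to horizon 3.
fixture_three_species <- function(lag = TRUE) {
  b2 <- if (lag) 0.4 else 1.0   # founder birth times; lag = FALSE makes
  b3 <- if (lag) 1.5 else 2.0   # both node-time conventions coincide
  lineages <- data.frame(
    id = 1:3, parent_id = c(NA, 1L, 1L),
    birth_time = c(0, b2, b3), death_time = NA_real_,
    species_at_birth = c(1L, 1L, 1L), species_final = 1:3,
    fate = "alive")
  species <- data.frame(
    species_id = 1:3, parent_species = c(NA, 1L, 1L),
    founder_lineage = 1:3, origin_time = c(0, 1, 2),
    extinction_time = NA_real_, n_incipient = 1L, extant = TRUE)
  events <- data.frame(
    time = c(b2, b3, 1, 2),
    kind = c("branch", "branch", "conversion", "conversion"),
    lineage_id = c(1L, 1L, 2L, 3L),
    species_id = c(1L, 1L, 1L, 1L),
    new_species_id = c(NA, NA, 2L, 3L))
  ord <- order(events$time)
  manual_sim(events = events[ord, ], species = species,
             lineages = lineages, horizon = 3, n_alive_final = 3L)
}

# Crown Yule branching times: splits simulated to the n-th birth, the tree
# observed during the interval with n lineages (duration Exp(n*lambda)).
sim_yule_bt <- function(n, lambda) {
  g <- stats::rexp(n - 1L, rate = (2:n) * lambda)  # g_2 .. g_n
  splits <- cumsum(g[seq_len(n - 2L)])             # times of splits to 3..n
  total <- sum(g)
  branching_times(total - c(0, splits))
}

# Reconstructed tree of a surviving birth-death replicate (>= min_tips).
sim_bd_tree <- function(lambda, mu, t_max, min_tips = 2L,
                        max_tries = 10000L) {
  repeat {
    r <- condition_on_survival(bd_params(lambda, mu, t_max),
                               max_tries = max_tries)
    if (r$n_alive_final >= min_tips)
      return(lineage_phylo(r, extant_only = TRUE))
  }
}

rescale_tree <- function(tree, c) {
  tree$edge.length <- tree$edge.length * c
  if (!is.null(tree$root.edge)) tree$root.edge <- tree$root.edge * c
  tree
}

# Brute-force Colless oracle: tip counts per internal node obtained by
# walking every tip's root path (independent of the postorder pass).
colless_oracle <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ntips <- integer(n + tree$Nnode)
  for (tip in seq_len(n)) {
    v <- tip
    while (v != 0L) {
      if (v > n) ntips[v] <- ntips[v] + 1L
      v <- parent[v]
    }
  }
  total <- 0L
  for (v in (n + 1L):(n + tree$Nnode)) {
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    kid_tips <- ifelse(ch <= n, 1L, ntips[ch])
    total <- total + abs(kid_tips[1L] - kid_tips[2L])
  }
  total
}

# Iterative grid-search maximizer of the Yule log-likelihood, refined over
# several rounds; independent route to the closed-form MLE.
yule_grid_mle <- function(bt, rounds = 5L, width = 1000L) {
  ll <- function(lambda) vapply(lambda, bd_loglik, numeric(1), mu = 0,
                                bt = bt)
  lo <- 1e-6; hi <- 10 * bt$n / bt$T
  for (i in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = width)
    best <- which.max(ll(grid))
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(width, best + 1L)]
  }
  (lo + hi) / 2
}

# Replays the event log and checks that every species disappearance is a
# loss event labelled species_extinction with zero members left behind.
check_emergent_extinction <- function(result) {
  ev <- result$events
  n_sp <- max(1L, ev$species_id, ev$new_species_id, na.rm = TRUE)
  counts <- integer(n_sp); counts[1L] <- 1L
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k == "branch") {
      s <- if (is.na(ev$new_species_id[i])) ev$species_id[i]
           else ev$new_species_id[i]
      counts[s] <- counts[s] + 1L
    } else if (k == "loss") {
      s <- ev$species_id[i]
      counts[s] <- counts[s] - 1L
      if (counts[s] == 0L) {
        if (!identical(ev$label[i], "species_extinction"))
          stop("species vanished without a species_extinction label")
      } else if (identical(ev$label[i], "species_extinction")) {
        stop("species_extinction label but members remain")
      }
    } else {
      s_old <- ev$species_id[i]; s_new <- ev$new_species_id[i]
      if (s_new != s_old) {
        counts[s_old] <- counts[s_old] - 1L
        counts[s_new] <- counts[s_new] + 1L
      }
      if (any(counts[c(s_old, s_new)] == 0L))
        stop("conversion emptied a species")
    }
    if (any(counts < 0L)) stop("negative membership during replay")
  }
  TRUE
}

# Node times (time from the origin) of every internal node of a tree built
# by the package (root.edge = origin offset).
internal_node_times <- function(tree) {
  off <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  n <- length(tree$tip.label)
  ape::node.depth.edgelength(tree)[(n + 1L):(n + tree$Nnode)] + off
}
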