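#' Lineage-through-time curve
#'
#' Counts lineages of a rooted, time-calibrated tree as a step function of
#' time from the origin (the \code{root.edge}, when present, places the
#' origin before the first split).  The count rises at every split and, for
#' complete (non-ultrametric) trees, falls at every extinct tip.  Polytomies
#' are allowed and contribute a step equal to their out-degree minus one.
#'
#' @param tree A \code{"phylo"} object with branch lengths.
#' @param extant_only Prune extinct tips first, giving the monotone curve of
#'   the reconstructed tree.
#' @return A data frame with columns \code{time} and \code{n_lineages},
#'   starting at \code{(origin, 1)}.
#' @examples
#' tr <- ape::read.tree(text = "((A:2,B:2):1,C:3);")
#' compute_ltt(tr)
#' @export
compute_ltt <- function(tree, extant_only = FALSE) {
  tree <- check_tree(tree)
  if (extant_only) tree <- prune_extinct(tree)
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    return(data.frame(time = 0, n_lineages = 1L))
  }
  offset <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  depth <- ape::node.depth.edgelength(tree) + offset
  horizon <- max(depth[seq_len(ntip)])
  tol <- 1e-9 * max(horizon, 1)
  # +(<out-degree> - 1) at internal nodes, -1 at extinct tips
  deg <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  node_ids <- which(deg > 0L)
  times <- depth[node_ids]
  steps <- deg[node_ids] - 1L
  extinct <- which(depth[seq_len(ntip)] < horizon - tol)
  if (length(extinct) > 0L) {
    times <- c(times, depth[extinct])
    steps <- c(steps, rep(-1L, length(extinct)))
  }
  agg <- rowsum(steps, group = times)
  t_ev <- as.numeric(rownames(agg))
  ord <- order(t_ev)
  data.frame(
    time = c(0, t_ev[ord]),
    n_lineages = unname(cumsum(c(1L, agg[ord, 1L]))),
    row.names = NULL)
}

#' Gamma statistic of an ultrametric tree
#'
#' The standardized summary of internode intervals: with \eqn{n} tips,
#' crown-to-tip intervals \eqn{g_2, \ldots, g_n} (the duration with
#' \eqn{j} lineages) and \eqn{T = \sum_{j=2}^n j g_j},
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i - T/2}
#'   {T\sqrt{1/(12(n-2))}}, \quad T_i = \sum_{j=2}^{i} j g_j.}
#' Negative values indicate branching concentrated early in the clade's
#' history (an "early burst"); under a pure-birth null the statistic is
#' approximately standard normal.  \eqn{\gamma} is invariant to rescaling
#' all branch lengths.
#'
#' @param tree An ultrametric \code{"phylo"} object with at least 3 tips;
#'   ultrametricity is checked to a relative tolerance of \code{1e-9} times
#'   the tree height.
#' @return The gamma statistic, a single number.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' gamma_statistic(tr)
#' @export
gamma_statistic <- function(tree) {
  tree <- check_tree(tree)
  n <- length(tree$tip.label)
  if (n < 3L) stop("gamma statistic requires at least 3 tips")
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n)])
  if (max(abs(depth[seq_len(n)] - height)) > 1e-9 * height)
    stop("tree is not ultrametric (tolerance 1e-9 * height)")
  node_times <- sort(depth[(n + 1L):(n + tree$Nnode)])  # crown first
  g <- diff(c(node_times, height))                      # g_2 .. g_n
  j <- 2:n
  Tsum <- sum(j * g)
  Ti <- cumsum(j * g)                                   # T_2 .. T_n
  (mean(Ti[seq_len(n - 2L)]) - Tsum / 2) / (Tsum * sqrt(1 / (12 * (n - 2))))
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference between the numbers
#' of tips descended from the two daughter branches.  Zero for a fully
#' balanced tree; \eqn{(n-1)(n-2)/2} for an n-tip caterpillar.  Polytomies
#' are rejected.
#'
#' @param tree A rooted, strictly binary \code{"phylo"} object.
#' @return A non-negative integer.
#' @examples
#' colless_index(ape::read.tree(text = "(((A,B),C),D);"))  # caterpillar: 3
#' @export
colless_index <- function(tree) {
  tree <- check_tree(tree, need_lengths = FALSE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  if (tree$Nnode != n - 1L)
    stop("tree has polytomies; the Colless index is defined for binary trees")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntips <- c(rep(1L, n), integer(tree$Nnode))
  imb <- 0L
  e <- tree$edge
  i <- 1L
  n_edge <- nrow(e)
  while (i <= n_edge) {
    p <- e[i, 1L]
    a <- ntips[e[i, 2L]]; b <- ntips[e[i + 1L, 2L]]
    ntips[p] <- a + b
    imb <- imb + abs(a - b)
    i <- i + 2L
  }
  imb
}

#' Distribution of incipient forms per species
#'
#' Histogram of the number of living incipient lineages per species at a
#' given time, with its mean, median and sample skewness.  The model
#' predicts a strongly uneven distribution: most species contain a single
#' incipient form while a few contain many, so the modal class is
#' \eqn{k = 1} and the skewness is positive.
#'
#' Skewness is the adjusted Fisher--Pearson estimator
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} with
#' \eqn{g_1 = m_3 / m_2^{3/2}}; it is reported as \code{NA} for fewer than
#' 3 species or zero variance.
#'
#' @param result An \code{"esm_sim"} object.
#' @param at_time Time in Myr within the simulated horizon.
#' @return An object of class \code{"incipient_histogram"}: a list with
#'   \code{counts} (data frame \code{k}, \code{n_species}), \code{mean},
#'   \code{median}, \code{skewness}, \code{n_species} and \code{at_time}.
#' @examples
#' res <- simulate_esm(esm_params(1, 0.5, 0.05, t_max = 6, seed = 2))
#' incipient_distribution(res, at_time = 6)
#' @export
incipient_distribution <- function(result, at_time = result$horizon) {
  k <- species_membership_counts(result, at_time)
  if (length(k) == 0L) stop("no species alive at 'at_time'")
  tab <- table(as.integer(k))
  structure(list(
    counts = data.frame(k = as.integer(names(tab)),
                        n_species = as.integer(tab)),
    mean = mean(k),
    median = stats::median(k),
    skewness = sample_skewness(as.numeric(k)),
    n_species = length(k),
    at_time = at_time), class = "incipient_histogram")
}

# adjusted Fisher-Pearson standardized third moment
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @export
print.incipient_histogram <- function(x, ...) {
  cat(sprintf("Incipient forms per species at t = %g (%d species)\n",
              x$at_time, x$n_species))
  cat(sprintf("  mean %.3f, median %g, skewness %s\n", x$mean, x$median,
              if (is.na(x$skewness)) "NA" else sprintf("%.3f", x$skewness)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Effective per-species speciation and extinction rates
#'
#' For each species: the effective speciation rate is the number of
#' conversions founded from its lineages divided by its total lineage-time
#' exposure (lineage-Myr spent inside the species); the effective
#' extinction exposure is the reciprocal of the expected time for all
#' \eqn{k} current members to be lost under the per-lineage loss rate
#' \eqn{\mu_i} alone, \eqn{\mu_i / H_k} with \eqn{H_k} the harmonic number
#' -- a decreasing function of membership, so species rich in incipient
#' forms are effectively protected from extinction.  No-op conversions
#' (drawn for a species' only member) are not counted as speciation.
#'
#' @param result An \code{"esm_sim"} object with a non-empty event log or
#'   at least one species interval.
#' @return A data frame with one row per species: \code{species_id},
#'   \code{exposure} (lineage-Myr), \code{n_conversions},
#'   \code{speciation_rate}, \code{n_incipient} (membership at the
#'   horizon), \code{extinction_exposure} (\code{NA} for extinct species).
#' @examples
#' res <- simulate_esm(esm_params(1, 0.5, 0.1, t_max = 8, seed = 3))
#' effective_rates(res)
#' @export
effective_rates <- function(result) {
  stopifnot(inherits(result, "esm_sim"))
  mb <- result$membership
  sp <- result$species
  exposure <- numeric(nrow(sp))
  agg <- rowsum(mb$t_to - mb$t_from, group = mb$species_id)
  exposure[as.integer(rownames(agg))] <- agg[, 1L]
  if (any(exposure <= 0))
    stop("species with zero lineage-time exposure")
  ev <- result$events
  conv <- ev[ev$kind == "conversion" & ev$new_species_id != ev$species_id, ,
             drop = FALSE]
  n_conv <- integer(nrow(sp))
  if (nrow(conv) > 0L) {
    tab <- table(conv$species_id)
    n_conv[as.integer(names(tab))] <- as.integer(tab)
  }
  mu_i <- if (result$model == "bd") result$params$mu else result$params$mu_i
  k <- sp$n_incipient
  ext_exp <- ifelse(k >= 1L,
                    mu_i / vapply(k, function(m)
                      if (m >= 1L) sum(1 / seq_len(m)) else NA_real_,
                      numeric(1)),
                    NA_real_)
  data.frame(
    species_id = sp$species_id,
    exposure = exposure,
    n_conversions = n_conv,
    speciation_rate = n_conv / exposure,
    n_incipient = k,
    extinction_exposure = ext_exp)
}

check_tree <- function(tree, need_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (need_lengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  }
  n <- length(tree$tip.label)
  # ape represents unrooted trees with a basal trichotomy; a 3-tip star is
  # indistinguishable from that and is accepted as a rooted star
  if (n > 3L && !ape::is.rooted(tree) && tree$Nnode == n - 2L)
    stop("tree must be rooted")
  tree
}
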