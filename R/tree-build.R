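# Build an ape "phylo" from a table of timed entities (species or lineages)
# in budding form: each entity has a parent, a start time (when it split off
# its parent's path) and an end time (extinction or horizon).  Every entity
# becomes one tip; every split becomes a binary internal node, so an entity
# with k children contributes a pectinate path of k nodes.  A positive time
# from the origin to the first split is stored as root.edge.

build_timed_phylo <- function(id, parent, t_start, t_end, tip_label) {
  n <- length(id)
  stopifnot(length(parent) == n, length(t_start) == n, length(t_end) == n)
  idx <- match(seq_len(max(id)), id)            # id -> row
  root_row <- which(is.na(parent))
  if (length(root_row) != 1L) stop("exactly one root entity required")

  if (n == 1L) {
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = t_end[1L] - t_start[1L],
      tip.label = tip_label[1L],
      Nnode = 1L), class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }

  # splits = non-root entities, ordered by attach time (ties: creation order,
  # so a parent created at the same instant precedes its children)
  child_rows <- setdiff(seq_len(n), root_row)
  ord <- child_rows[order(t_start[child_rows], id[child_rows])]
  n_int <- length(ord)                          # internal nodes, root first

  edge_from <- integer(2L * n - 2L); edge_to <- integer(2L * n - 2L)
  edge_len <- numeric(2L * n - 2L)
  n_edge <- 0L

  attach_node <- integer(n)                     # 0 = hangs from the origin
  seg_start <- numeric(n)
  attach_node[root_row] <- 0L
  seg_start[root_row] <- t_start[root_row]
  root_edge <- 0

  for (j in seq_len(n_int)) {
    ch <- ord[j]
    pa <- idx[parent[ch]]
    v <- n + j                                  # internal node number
    tau <- t_start[ch]
    if (attach_node[pa] == 0L) {
      root_edge <- tau - seg_start[pa]
    } else {
      n_edge <- n_edge + 1L
      edge_from[n_edge] <- attach_node[pa]; edge_to[n_edge] <- v
      edge_len[n_edge] <- tau - seg_start[pa]
    }
    attach_node[pa] <- v; seg_start[pa] <- tau
    attach_node[ch] <- v; seg_start[ch] <- tau
  }

  for (i in seq_len(n)) {                       # terminal segments
    n_edge <- n_edge + 1L
    edge_from[n_edge] <- attach_node[i]; edge_to[n_edge] <- i
    edge_len[n_edge] <- t_end[i] - seg_start[i]
  }

  tr <- structure(list(
    edge = cbind(edge_from[seq_len(n_edge)], edge_to[seq_len(n_edge)]),
    edge.length = edge_len[seq_len(n_edge)],
    tip.label = tip_label,
    Nnode = n_int), class = "phylo")
  if (root_edge > 0) tr$root.edge <- root_edge
  tr
}

# Drop extinct tips (those not reaching the maximum depth within tol) and
# restore root.edge so the origin of the pruned tree is unchanged.
prune_extinct <- function(tree, origin_height = NULL, tol = 1e-9) {
  depth <- ape::node.depth.edgelength(tree)
  offset <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  tip_depth <- depth[seq_along(tree$tip.label)] + offset
  height <- if (is.null(origin_height)) max(tip_depth) else origin_height
  extinct <- tree$tip.label[tip_depth < height - tol * max(height, 1)]
  if (length(extinct) == 0L) return(tree)
  if (length(extinct) == length(tree$tip.label))
    stop("no extant tips to keep")
  if (length(tree$tip.label) - length(extinct) == 1L) {
    keep <- setdiff(tree$tip.label, extinct)
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = height,
      tip.label = keep,
      Nnode = 1L), class = "phylo")
    return(tr)
  }
  out <- ape::drop.tip(tree, extinct)
  new_height <- max(ape::node.depth.edgelength(out))
  re <- height - new_height
  if (re > tol * max(height, 1)) out$root.edge <- re else out$root.edge <- NULL
  out
}

#' Incipient-lineage genealogy as a phylogenetic tree
#'
#' Converts the budding genealogy of incipient lineages into a binary
#' \code{"phylo"} object: each lineage becomes one tip (labelled
#' \code{lin<id>}) and each branching a binary node.  Time from the origin
#' to the first branching is kept as \code{root.edge}.
#'
#' @param result An \code{"esm_sim"} object.
#' @param extant_only Drop lineages not alive at the horizon (the
#'   reconstructed tree).  Requires at least one survivor.
#' @return An \code{ape} \code{"phylo"} object with a \code{node_data}
#'   attribute carrying per-tip \code{fate} and species membership.
#' @seealso [collapse_to_species_tree()]
#' @export
lineage_phylo <- function(result, extant_only = FALSE) {
  stopifnot(inherits(result, "esm_sim"))
  ln <- result$lineages
  t_end <- ifelse(is.na(ln$death_time), result$horizon, ln$death_time)
  tr <- build_timed_phylo(ln$id, ln$parent_id, ln$birth_time, t_end,
                          paste0("lin", ln$id))
  nd <- data.frame(node = match(paste0("lin", ln$id), tr$tip.label),
                   fate = ln$fate,
                   species_id = ln$species_final)
  attr(tr, "node_data") <- nd[order(nd$node), , drop = FALSE]
  if (extant_only) {
    if (!result$surviving) stop("no lineage alive at the horizon")
    tr <- prune_extinct(tr, origin_height = result$horizon)
    nd <- attr(tr, "node_data")  # dropped by prune; rebuild for kept tips
    keep <- match(tr$tip.label, paste0("lin", ln$id))
    attr(tr, "node_data") <- data.frame(
      node = seq_along(tr$tip.label),
      fate = ln$fate[keep],
      species_id = ln$species_final[keep])
  }
  tr
}
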