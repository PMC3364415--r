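# Annotated Newick I/O.  Plain topology and branch lengths follow the
# standard Newick grammar; per-node annotations travel in NHX-style comment
# blocks ("[&&NHX:key=value:key=value]") placed after the branch length.
# ape reads and writes plain Newick but discards comments, so the annotated
# round trip is implemented here; plain output is cross-checked against
# ape in the tests.

#' Write a tree to a Newick file, optionally with NHX annotations
#'
#' Branch lengths are printed with 15 significant digits, enough for a
#' lossless round trip at \code{1e-12} relative tolerance.  Annotations are
#' taken from the tree's \code{node_data} attribute (a data frame whose
#' \code{node} column holds ape node numbers; remaining columns become NHX
#' keys).
#'
#' @param tree A \code{"phylo"} object.
#' @param path Output file path; \code{""} returns the string invisibly
#'   without writing.
#' @param annotations Write the \code{node_data} attribute as NHX comments.
#' @return The Newick string, invisibly.
#' @seealso [read_newick()]
#' @export
write_newick <- function(tree, path, annotations = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  annot <- rep("", n + tree$Nnode)
  nd <- attr(tree, "node_data")
  if (annotations && !is.null(nd) && nrow(nd) > 0L) {
    keys <- setdiff(names(nd), "node")
    for (i in seq_len(nrow(nd))) {
      vals <- vapply(keys, function(k) format_nhx_value(nd[[k]][i]),
                     character(1))
      annot[nd$node[i]] <-
        paste0("[&&NHX:", paste0(keys, "=", vals, collapse = ":"), "]")
    }
  }
  fmt <- function(x) sprintf("%.15g", x)

  if (n == 1L && nrow(tree$edge) == 1L) {
    s <- paste0(tree$tip.label[1L], ":", fmt(tree$edge.length[1L]),
                annot[1L], ";")
  } else {
    lab <- gsub("[(),:;\\[\\] ]", "_", tree$tip.label, perl = TRUE)
    piece <- character(n + tree$Nnode)
    piece[seq_len(n)] <- lab
    elen <- character(n + tree$Nnode)
    elen[tree$edge[, 2L]] <- paste0(":", fmt(tree$edge.length))
    po <- ape::reorder.phylo(tree, "postorder")
    parents <- unique(po$edge[, 1L])            # every parent after its kids
    kids <- split(po$edge[, 2L], factor(po$edge[, 1L], levels = parents))
    for (p in parents) {
      ch <- kids[[as.character(p)]]
      piece[p] <- paste0("(",
                         paste0(piece[ch], elen[ch], annot[ch],
                                collapse = ","),
                         ")")
    }
    root <- n + 1L
    s <- paste0(piece[root],
                if (!is.null(tree$root.edge))
                  paste0(":", fmt(tree$root.edge)) else "",
                annot[root], ";")
  }
  if (nzchar(path)) writeLines(s, path)
  invisible(s)
}

format_nhx_value <- function(v) {
  if (is.logical(v)) return(if (v) "1" else "0")
  if (is.numeric(v)) return(sprintf("%.15g", v))
  gsub("[:=\\[\\]]", "_", as.character(v), perl = TRUE)
}

#' Read a Newick file, keeping NHX annotations
#'
#' A stack-based parser for rooted Newick with branch lengths, node labels
#' and NHX-style comment blocks.  Malformed input raises an error naming
#' the character offset.  Unknown annotation keys are kept (they are not
#' interpreted); non-NHX comments are ignored with a warning.
#'
#' @param path Path to a Newick file, or a literal string containing ";".
#' @return A \code{"phylo"} object; annotations, if present, are in the
#'   \code{node_data} attribute (all values as character).
#' @seealso [write_newick()]
#' @export
read_newick <- function(path) {
  s <- if (grepl(";", path, fixed = TRUE)) path
       else paste(readLines(path, warn = FALSE), collapse = "")
  s <- gsub("[[:space:]]+", "", s)
  n_char <- nchar(s)
  if (n_char == 0L) stop("empty Newick input")

  # node store
  cap <- 64L
  nd_parent <- rep(NA_integer_, cap); nd_len <- rep(NA_real_, cap)
  nd_label <- rep(NA_character_, cap); nd_annot <- rep(NA_character_, cap)
  nd_is_tip <- logical(cap); nd_order <- integer(cap)
  n_nodes <- 0L
  new_node <- function(parent, is_tip) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > cap) {
      cap <<- 2L * cap
      length(nd_parent) <<- cap; length(nd_len) <<- cap
      length(nd_label) <<- cap; length(nd_annot) <<- cap
      length(nd_is_tip) <<- cap; length(nd_order) <<- cap
    }
    nd_parent[n_nodes] <<- parent
    nd_is_tip[n_nodes] <<- is_tip
    n_nodes
  }

  stack <- integer(0)
  cur <- NA_integer_
  i <- 1L
  bad <- function(msg, at) stop(sprintf(
    "malformed Newick at character %d: %s", at, msg), call. = FALSE)

  while (i <= n_char) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      top <- if (length(stack)) stack[length(stack)] else NA_integer_
      stack <- c(stack, new_node(top, FALSE))
      cur <- NA_integer_                        # next name token is a tip
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) bad("unmatched ')'", i)
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ",") {
      if (length(stack) == 0L) bad("',' outside parentheses", i)
      cur <- NA_integer_
      i <- i + 1L
    } else if (ch == ":") {
      if (is.na(cur)) bad("branch length with no node", i)
      rest <- substr(s, i + 1L, n_char)
      m <- regmatches(rest, regexpr("^[-+0-9.eE]+", rest))
      if (length(m) == 0L || is.na(suppressWarnings(as.numeric(m))))
        bad("unparseable branch length", i + 1L)
      nd_len[cur] <- as.numeric(m)
      i <- i + 1L + nchar(m)
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n_char), fixed = TRUE)
      if (j < 0L) bad("unterminated comment", i)
      com <- substr(s, i + 1L, i + j - 2L)
      if (startsWith(com, "&&NHX")) {
        if (is.na(cur)) bad("annotation with no node", i)
        nd_annot[cur] <- sub("^&&NHX:?", "", com)
      } else {
        warning(sprintf("ignoring non-NHX comment at character %d", i))
      }
      i <- i + j
    } else if (ch == ";") {
      if (length(stack) != 0L) bad("unmatched '('", i)
      break
    } else {
      rest <- substr(s, i, n_char)
      m <- regmatches(rest,
                      regexpr("^[^(),:;\\[\\]]+", rest, perl = TRUE))
      if (length(m) == 0L) bad("unexpected character", i)
      if (!is.na(cur) && !nd_is_tip[cur]) {
        # label directly after ')': internal node label
        nd_label[cur] <- m
      } else {
        top <- if (length(stack)) stack[length(stack)] else NA_integer_
        cur <- new_node(top, TRUE)
        nd_label[cur] <- m
      }
      i <- i + nchar(m)
    }
  }
  if (length(stack) != 0L) bad("unmatched '(' at end of input", n_char)
  if (n_nodes == 0L) bad("no nodes parsed", 1L)

  build_phylo_from_parse(n_nodes, nd_parent, nd_len, nd_label, nd_annot,
                         nd_is_tip)
}

build_phylo_from_parse <- function(n_nodes, parent, len, label, annot,
                                   is_tip) {
  idx <- seq_len(n_nodes)
  tips <- idx[is_tip[idx]]
  internals <- idx[!is_tip[idx]]
  n_tip <- length(tips)

  if (n_tip == 1L && length(internals) == 0L) {
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = if (is.na(len[tips])) 0 else len[tips],
      tip.label = label[tips],
      Nnode = 1L), class = "phylo")
    tr <- attach_node_data(tr, annot[tips], 1L)
    return(tr)
  }
  if (n_tip < 2L) stop("malformed Newick: fewer than 2 tips")

  # renumber: tips 1..n in parse order, root n+1, internals in parse order
  num <- integer(n_nodes)
  num[tips] <- seq_len(n_tip)
  num[internals] <- n_tip + seq_along(internals)  # parse order: root first
  has_parent <- !is.na(parent[idx])
  edge <- cbind(num[parent[idx][has_parent]], num[idx][has_parent])
  elen <- len[idx][has_parent]
  if (all(is.na(elen))) elen <- NULL
  else elen[is.na(elen)] <- 0

  tr <- structure(list(
    edge = edge,
    tip.label = label[tips],
    Nnode = length(internals)), class = "phylo")
  if (!is.null(elen)) tr$edge.length <- elen
  root <- internals[is.na(parent[internals])]
  if (!is.na(len[root]) && len[root] > 0) tr$root.edge <- len[root]
  if (any(!is.na(label[internals])))
    tr$node.label <- label[internals]
  ord <- c(tips, internals)
  attach_node_data(tr, annot[ord], num[ord])
}

attach_node_data <- function(tr, annot, node_num) {
  has <- !is.na(annot)
  if (!any(has)) return(tr)
  recs <- lapply(which(has), function(i) {
    kv <- strsplit(annot[i], ":", fixed = TRUE)[[1]]
    kv <- kv[nzchar(kv)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    vals <- vapply(parts, function(p) paste(p[-1L], collapse = "="),
                   character(1))
    names(vals) <- vapply(parts, `[`, character(1), 1L)
    c(node = node_num[i], as.list(vals))
  })
  keys <- unique(unlist(lapply(recs, names)))
  nd <- do.call(rbind, lapply(recs, function(r) {
    row <- as.data.frame(r[intersect(keys, names(r))],
                         stringsAsFactors = FALSE)
    for (k in setdiff(keys, names(r))) row[[k]] <- NA_character_
    row[keys]
  }))
  nd$node <- as.integer(nd$node)
  attr(tr, "node_data") <- nd[order(nd$node), , drop = FALSE]
  tr
}
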