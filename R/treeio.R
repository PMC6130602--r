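#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream likelihood machinery relies on: unique non-empty tip labels,
#' finite non-negative branch lengths on every edge (a missing length on the
#' root edge is tolerated and treated as zero). Polytomies are accepted and
#' preserved; bracketed Newick comments are ignored by the parser.
#'
#' @param source path to a Newick file, or a Newick string (recognised by the
#'   presence of `(` and `;`).
#' @return an object of class `"phylo"`.
#' @export
read_newick <- function(source) {
  is_text <- length(source) == 1L && grepl("\\(", source) && grepl(";", source)
  tree <- if (is_text) ape::read.tree(text = source) else ape::read.tree(source)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (!is.null(tree$root.edge)) tree$root.edge <- NULL
  validate_tree(tree)
  tree
}

#' Write a tree to Newick
#'
#' @param tree a `"phylo"` object.
#' @param path output file; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Validate tree invariants
#'
#' Checks that tip labels are unique and non-empty and that all branch
#' lengths are finite and non-negative. Called by all rooting and likelihood
#' entry points.
#'
#' @param tree a `"phylo"` object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate tip label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (any(!nzchar(labs))) stop("empty tip label")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  el <- tree$edge.length
  if (anyNA(el) || any(!is.finite(el))) stop("non-finite branch length")
  if (any(el < 0)) stop("negative branch length")
  invisible(tree)
}

#' Tip-to-tip path lengths
#'
#' @param tree a `"phylo"` object.
#' @return symmetric matrix of patristic distances between tips.
#' @export
tip_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path, so the two
#' maximal root-to-tip distances are equal.
#'
#' @param tree a `"phylo"` object with at least two tips.
#' @return a rooted `"phylo"` object with the same tip set and pairwise
#'   patristic distances.
#' @export
midpoint_root <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  if (sum(tree$edge.length) <= 0) stop("all branch lengths are zero; midpoint undefined")
  if (length(tree$tip.label) == 2L) {
    d <- sum(tree$edge.length)
    out <- ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);",
                                         tree$tip.label[1], d / 2,
                                         tree$tip.label[2], d / 2))
    return(out)
  }
  phangorn::midpoint(tree)
}

# undirected adjacency list of an unrooted tree: for vertex v, rows (nbr, len)
.adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; l <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }
  adj
}

# Re-root an (unrooted) tree at a point `pos` along edge e = (u, v), measured
# from u. If the point coincides with an endpoint the root is placed at that
# vertex instead of introducing a zero-length edge.
.root_at_point <- function(tree, edge_idx, pos, tol = 1e-12) {
  u <- tree$edge[edge_idx, 1]; v <- tree$edge[edge_idx, 2]
  l <- tree$edge.length[edge_idx]
  ntip <- length(tree$tip.label)
  adj <- .adjacency(tree)
  # never root exactly at a tip: pull the point just inside the branch
  if (v <= ntip && pos >= l - tol) pos <- max(l / 2, l - 10 * tol)

  # children lists keyed by old vertex id; root is either an old vertex or
  # the synthetic id 0
  if (pos <= tol) {
    root_old <- u; extra <- NULL
  } else if (pos >= l - tol) {
    root_old <- v; extra <- NULL
  } else {
    root_old <- 0L
    extra <- list(c(u, pos), c(v, l - pos))
  }

  # iterative DFS from the root over the undirected graph, skipping the
  # split edge when the root is interior to it
  n_old <- ntip + tree$Nnode
  new_id <- integer(n_old + 1L)  # +1 slot for synthetic root id 0 -> index n_old+1
  idx_of <- function(vv) if (vv == 0L) n_old + 1L else vv
  next_internal <- ntip + 1L
  new_id[idx_of(root_old)] <- next_internal
  next_internal <- next_internal + 1L

  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  # stack rows: (old vertex, old parent vertex)
  stack <- list()
  push_children <- function(vv, parent, stack) {
    if (vv == 0L) {
      for (x in extra) stack[[length(stack) + 1L]] <- c(x[1], 0L, x[2])
      return(stack)
    }
    nb <- adj[[vv]]
    if (is.null(nb)) return(stack)
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (w == parent) next
      # skip the split edge when root is interior
      if (root_old == 0L &&
          ((vv == u && w == v) || (vv == v && w == u)))
        next
      stack[[length(stack) + 1L]] <- c(w, vv, nb[r, 2])
    }
    stack
  }
  stack <- push_children(root_old, -1L, stack)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    w <- as.integer(top[1]); p <- as.integer(top[2]); len <- top[3]
    if (w <= ntip) {
      new_id[w] <- w
    } else {
      new_id[w] <- next_internal
      next_internal <- next_internal + 1L
    }
    edges <- rbind(edges, c(new_id[idx_of(p)], new_id[w]))
    lens <- c(lens, len)
    stack <- push_children(w, p, stack)
  }

  out <- list(edge = edges, edge.length = lens,
              tip.label = tree$tip.label,
              Nnode = next_internal - 1L - ntip)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Minimal ancestor deviation (MAD) rooting
#'
#' For every candidate root position on every branch of the unrooted tree,
#' computes the root-mean-square relative deviation of induced
#' ancestor-descendant distances over all tip pairs
#' (`rho = |2 d(ancestor, tip) / d(tip, tip') - 1|`) and roots at the
#' minimising position. The optimal position within a branch is found in
#' closed form (the cross-pair contribution is quadratic in the position);
#' ties between branches are broken deterministically in favour of the first
#' branch in postorder traversal. On a clock-like tree the objective is zero
#' at the original root, which is therefore recovered.
#'
#' @param tree a `"phylo"` object with at least three tips and positive total
#'   branch length.
#' @return a rooted `"phylo"` object; attributes `mad_objective` (the RMS
#'   deviation attained) and `mad_rho` (relative position on the chosen
#'   branch) are attached.
#' @export
mad_root <- function(tree) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 tips")
  if (sum(tree$edge.length) <= 0) stop("total branch length must be positive")

  tu <- ape::unroot(tree)
  tu <- ape::reorder.phylo(tu, "postorder")
  D <- ape::dist.nodes(tu)
  tips <- seq_len(ntip)
  Dt <- D[tips, tips, drop = FALSE]
  if (all(Dt == 0)) {
    warning("all tip-to-tip distances are zero; falling back to midpoint rooting")
    return(midpoint_root(tree))
  }

  npair <- ntip * (ntip - 1) / 2
  best <- list(obj = Inf, edge = NA_integer_, pos = 0, rho = 0)
  for (e in seq_len(nrow(tu$edge))) {
    u <- tu$edge[e, 1]; v <- tu$edge[e, 2]; l <- tu$edge.length[e]
    # tips on the v side of the edge: strictly closer to v than to u
    side_v <- tips[D[tips, v] < D[tips, u]]
    side_u <- setdiff(tips, side_v)
    if (!length(side_v) || !length(side_u)) next

    # same-side pairs: ancestor fixed by geometry, independent of position
    ss <- 0
    for (side in list(c(1, u), c(2, v))) {
      S <- if (side[1] == 1) side_u else side_v
      w <- side[2]
      if (length(S) >= 2) {
        cmb <- combn(S, 2)
        b <- cmb[1, ]; cc <- cmb[2, ]
        dbc <- Dt[cbind(b, cc)]
        dab <- (D[b, w] + dbc - D[cc, w]) / 2
        ok <- dbc > 0
        ss <- ss + sum((2 * dab[ok] / dbc[ok] - 1)^2)
      }
    }
    # cross pairs: r = 2 (d(u,b) + pos) / d(b,c) - 1 for b on the u side
    bu <- rep(side_u, times = length(side_v))
    cv <- rep(side_v, each = length(side_u))
    dbc <- Dt[cbind(bu, cv)]
    ok <- dbc > 0
    dbc <- dbc[ok]
    dub <- D[cbind(bu[ok], rep(u, sum(ok)))]
    vv <- 2 * dub / dbc - 1
    uu <- 2 / dbc
    # minimise sum (vv + pos * uu)^2 over pos in [0, l]
    pos <- if (sum(uu^2) > 0) -sum(uu * vv) / sum(uu^2) else 0
    pos <- min(max(pos, 0), l)
    obj <- sqrt((ss + sum((vv + pos * uu)^2)) / npair)
    if (obj < best$obj - 1e-12) {
      best <- list(obj = obj, edge = e, pos = pos,
                   rho = if (l > 0) pos / l else 0)
    }
  }
  if (!is.finite(best$obj)) {
    warning("degenerate tree; falling back to midpoint rooting")
    return(midpoint_root(tree))
  }
  out <- .root_at_point(tu, best$edge, best$pos)
  attr(out, "mad_objective") <- best$obj
  attr(out, "mad_rho") <- best$rho
  out
}
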