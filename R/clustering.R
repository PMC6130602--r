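#' Convert an LR matrix into a distance matrix
#'
#' Distances are the likelihood-ratio statistics subtracted from the largest
#' such statistic: `d(i, j) = max(LR) - LR(i, j)` for `i != j`, and
#' `d(i, i) = 0`. Strongly co-evolving pairs (large LR) therefore get small
#' distances, and adding a constant to every LR leaves the distances
#' unchanged.
#'
#' @param lr symmetric numeric LR matrix (e.g. from [all_pairs_lrt()]).
#' @return symmetric distance matrix with zero diagonal.
#' @export
lr_to_distance <- function(lr) {
  lr <- as.matrix(lr)
  if (nrow(lr) != ncol(lr)) stop("LR matrix must be square")
  bad <- which(is.na(lr) & row(lr) != col(lr), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("NaN/NA LR entries for pair(s): ",
         paste(apply(bad[bad[, 1] < bad[, 2], , drop = FALSE], 1,
                     paste, collapse = ","), collapse = "; "))
  }
  off <- lr[row(lr) != col(lr)]
  d <- max(off) - lr
  diag(d) <- 0
  d
}

#' UPGMA clustering of profiles
#'
#' Between-group average linkage: at each step the two clusters with the
#' smallest unweighted arithmetic mean of cross-pair distances are merged,
#' and the merge height is that mean distance (not halved). Leaves are
#' ordered lexically by profile id before clustering so ties are resolved
#' deterministically.
#'
#' @param d symmetric zero-diagonal distance matrix (e.g. from
#'   [lr_to_distance()]) with profile ids as dimnames, or a `"dist"`.
#' @return an object of class `"coevo_dendro"` wrapping the `"hclust"` tree.
#' @export
profile_upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least two profiles to cluster")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  ids <- rownames(d)
  if (is.null(ids)) ids <- colnames(d) <- rownames(d) <- paste0("p", seq_len(nrow(d)))
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(d), method = "average")
  structure(list(hclust = hc, ids = hc$labels), class = "coevo_dendro")
}

#' @export
print.coevo_dendro <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d profiles; merge heights in [%.4g, %.4g]\n",
              length(x$ids), min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram at height h
#'
#' Clusters are the sets of leaves joined only by merges with height `<= h`.
#' Raising `h` can only merge clusters, never split them; `h = 0` yields
#' singletons (for distinct profiles at positive distances) and any `h` at
#' or above the last merge yields a single cluster.
#'
#' @param dend a `"coevo_dendro"`.
#' @param h non-negative cut height on the LR-distance scale.
#' @return named integer vector mapping profile id to cluster id.
#' @export
cut_clusters <- function(dend, h) {
  stopifnot(inherits(dend, "coevo_dendro"), h >= 0)
  cutree(dend$hclust, h = h)
}

#' Cluster sizes of an assignment
#'
#' @param assignment named vector from [cut_clusters()].
#' @return integer vector of cluster sizes, named by cluster id.
#' @export
cluster_sizes <- function(assignment) {
  tab <- table(assignment)
  setNames(as.integer(tab), names(tab))
}

#' Merge table of a dendrogram
#'
#' @param dend a `"coevo_dendro"`.
#' @return data.frame with one row per merge: `step`, `left`, `right`
#'   (negative values index leaves by id, positive values earlier merge
#'   steps), `height` and `size` of the merged cluster.
#' @export
merge_table <- function(dend) {
  hc <- dend$hclust
  n <- length(hc$labels)
  sizes <- integer(nrow(hc$merge))
  lab <- function(v) if (v < 0) hc$labels[-v] else paste0("step", v)
  sz <- function(v) if (v < 0) 1L else sizes[v]
  out <- data.frame(step = seq_len(nrow(hc$merge)),
                    left = vapply(hc$merge[, 1], lab, character(1)),
                    right = vapply(hc$merge[, 2], lab, character(1)),
                    height = hc$height,
                    size = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(hc$merge))) {
    sizes[k] <- sz(hc$merge[k, 1]) + sz(hc$merge[k, 2])
    out$size[k] <- sizes[k]
  }
  out
}

#' Export a dendrogram as Newick with merge heights
#'
#' Branch lengths are differences of merge heights, so the path from the
#' root to any leaf sums to the final merge height and cophenetic distances
#' on the exported tree equal twice the half-height ultrametric convention
#' used by [ape::as.phylo.hclust()].
#'
#' @param dend a `"coevo_dendro"`.
#' @param path optional output file.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendro_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  write_newick(phy, path)
}
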