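#' Parse a Gene Ontology OBO file
#'
#' Minimal OBO 1.2 reader for `[Term]` stanzas: collects term ids, names,
#' namespaces and the `is_a` / `relationship: part_of` edges used by the
#' Wang semantic-similarity measure. Obsolete terms are dropped, as are
#' `alt_id`s; the DAG may be restricted to one namespace (default
#' `biological_process`). Edges point child to parent; acyclicity is
#' verified by topological sort.
#'
#' @param path OBO file.
#' @param namespace namespace to keep, or `NULL` for all.
#' @param weights named semantic contribution weights per edge type; the
#'   Wang/G-SESAME defaults are 0.8 for `is_a` and 0.6 for `part_of`.
#' @return object of class `"go_dag"`.
#' @export
parse_obo <- function(path, namespace = "biological_process",
                      weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flushterm <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete))
      terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flushterm(cur, terms)
      cur <- list(parents = character(), relation = character())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # other stanza type
      terms <- flushterm(cur, terms)
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:"))
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_obsolete:"))
      cur$obsolete <- grepl("true", ln)
    else if (startsWith(ln, "is_a:")) {
      p <- trimws(sub("^is_a:", "", ln))
      p <- strsplit(p, "\\s+")[[1]][1]
      cur$parents <- c(cur$parents, p)
      cur$relation <- c(cur$relation, "is_a")
    } else if (startsWith(ln, "relationship:")) {
      f <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(f) >= 2 && f[1] == "part_of") {
        cur$parents <- c(cur$parents, f[2])
        cur$relation <- c(cur$relation, "part_of")
      }
    }
  }
  terms <- flushterm(cur, terms)
  if (!length(terms)) stop("no terms parsed from ", path)
  if (!is.null(namespace)) {
    keep <- vapply(terms, function(t)
      is.null(t$namespace) || t$namespace == namespace, logical(1))
    terms <- terms[keep]
  }
  ids <- names(terms)
  parents <- lapply(terms, function(t) {
    ok <- t$parents %in% ids  # drop edges out of the kept namespace
    list(parent = t$parents[ok], relation = t$relation[ok])
  })
  names(parents) <- ids

  # topological order (children before parents) + cycle check
  nparent_of <- lengths(lapply(parents, `[[`, "parent"))
  children <- setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]$parent)
    children[[p]] <- c(children[[p]], id)
  indeg <- setNames(integer(length(ids)), ids)  # number of children pending
  for (id in ids) indeg[id] <- length(children[[id]])
  queue <- ids[indeg == 0]
  topo <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (p in parents[[v]]$parent) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(ids)) stop("cycle detected in ontology graph")
  if (!any(nparent_of == 0)) stop("ontology has no root term")
  structure(list(
    ids = ids,
    name = setNames(vapply(terms, function(t) t$name %||% "", character(1)), ids),
    namespace = setNames(vapply(terms, function(t) t$namespace %||% "", character(1)), ids),
    parents = parents, children = children, topo = topo,
    weights = weights), class = "go_dag")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.go_dag <- function(x, ...) {
  ne <- sum(lengths(lapply(x$parents, `[[`, "parent")))
  cat(sprintf("go_dag: %d terms, %d edges\n", length(x$ids), ne))
  invisible(x)
}

#' Ancestor closure of a term
#'
#' @param dag a `"go_dag"`.
#' @param term term id.
#' @return character vector of the term and all its ancestors.
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$ids) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, function(t)
      dag$parents[[t]]$parent))), seen)
  }
  seen
}

# Wang semantic contributions S_A(t) for all ancestors t of `term`:
# S(term) = 1, S(parent) = max over in-edges of w_e * S(child), propagated in
# topological order (children before parents).
.s_values <- function(dag, term) {
  anc <- ancestors(dag, term)
  S <- setNames(numeric(length(anc)), anc)
  S[term] <- 1
  for (v in dag$topo) {
    if (!v %in% anc || S[v] == 0) next
    pr <- dag$parents[[v]]
    for (k in seq_along(pr$parent)) {
      p <- pr$parent[k]
      w <- dag$weights[[pr$relation[k]]]
      val <- w * S[v]
      if (val > S[p]) S[p] <- val
    }
  }
  S
}

#' Wang/G-SESAME semantic similarity between two GO terms
#'
#' Each term `A` induces semantic contributions `S_A(t)` over its ancestor
#' set: `S_A(A) = 1` and `S_A(t) = max over child edges of w_e * S_A(child)`,
#' with edge weights 0.8 (`is_a`) and 0.6 (`part_of`) by default. With
#' `SV(A) = sum of S_A(t)`, the similarity is the aggregate contribution of
#' the shared ancestors:
#' `sim(a, b) = sum over shared t of (S_a(t) + S_b(t)) / (SV(a) + SV(b))`.
#' Symmetric, in `[0, 1]`, equal to 1 on identical terms.
#'
#' @param dag a `"go_dag"`.
#' @param a,b term ids.
#' @return similarity in `[0, 1]`.
#' @export
term_similarity <- function(dag, a, b) {
  Sa <- .s_values(dag, a)
  Sb <- .s_values(dag, b)
  shared <- intersect(names(Sa), names(Sb))
  if (!length(shared)) return(0)
  sum(Sa[shared] + Sb[shared]) / (sum(Sa) + sum(Sb))
}

# similarity matrix over a set of terms, with cached S-values
.term_sim_matrix <- function(dag, terms) {
  sv <- lapply(terms, function(t) .s_values(dag, t))
  names(sv) <- terms
  n <- length(terms)
  M <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      Sa <- sv[[i]]; Sb <- sv[[j]]
      shared <- intersect(names(Sa), names(Sb))
      s <- if (length(shared)) sum(Sa[shared] + Sb[shared]) / (sum(Sa) + sum(Sb)) else 0
      M[i, j] <- M[j, i] <- s
    }
  }
  M
}

#' Read a gene-to-GO annotation table
#'
#' Two-column TSV (gene id, GO term id; one pair per line, no header or a
#' `gene`/`term` header). Terms absent from the DAG are dropped with a
#' warning.
#'
#' @param path annotation TSV.
#' @param dag optional `"go_dag"` used to validate terms.
#' @return named list: gene id -> character vector of term ids.
#' @export
read_annotations <- function(path, dag = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   col.names = c("gene", "term"))
  if (df$gene[1] == "gene") df <- df[-1, , drop = FALSE]
  annot <- split(df$term, df$gene)
  annot <- lapply(annot, unique)
  if (!is.null(dag)) annot <- validate_annotations(annot, dag)
  annot
}

#' @rdname read_annotations
#' @param annot named list gene -> term ids.
#' @export
validate_annotations <- function(annot, dag) {
  known <- dag$ids
  out <- lapply(annot, function(ts) ts[ts %in% known])
  nd <- sum(lengths(annot)) - sum(lengths(out))
  if (nd > 0) warning(nd, " annotation(s) referenced unknown terms and were dropped")
  out[lengths(out) > 0]
}

#' Semantic similarity between two genes (best-match average)
#'
#' G-SESAME gene-level combination of term similarities:
#' `sim(G1, G2) = (sum over t in G1 of max_u sim(t, u) + sum over u in G2 of
#' max_t sim(t, u)) / (|G1| + |G2|)`.
#'
#' @param dag a `"go_dag"`.
#' @param annot named list gene -> term ids.
#' @param g1,g2 gene ids; both must carry at least one known term.
#' @return similarity in `[0, 1]`.
#' @export
gene_similarity <- function(dag, annot, g1, g2) {
  t1 <- annot[[g1]]; t2 <- annot[[g2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2))
    stop("both genes must be annotated")
  M <- .term_sim_matrix(dag, unique(c(t1, t2)))
  .bma(M, t1, t2)
}

.bma <- function(M, t1, t2) {
  sub <- M[t1, t2, drop = FALSE]
  (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) / (length(t1) + length(t2))
}

#' Size-weighted GO semantic score of a clustering
#'
#' Per-cluster score: mean best-match-average gene similarity over all
#' within-cluster pairs of annotated genes. Overall score: mean of the
#' per-cluster scores weighted by the number of annotated genes. Clusters
#' with fewer than two annotated genes (including singletons) are not
#' scoreable and are excluded from the weighted mean; their ids are
#' reported.
#'
#' @param dag a `"go_dag"`.
#' @param annot named list gene -> term ids.
#' @param clusters named vector gene -> cluster id.
#' @return list with `overall`, `per_cluster` (named numeric),
#'   `weights` (annotated genes per scoreable cluster) and `unscored`
#'   (cluster ids excluded).
#' @export
clustering_score <- function(dag, annot, clusters) {
  genes <- intersect(names(clusters), names(annot))
  genes <- genes[lengths(annot[genes]) > 0]
  if (!length(genes)) stop("no annotated genes in the clustering")
  terms <- unique(unlist(annot[genes], use.names = FALSE))
  M <- .term_sim_matrix(dag, terms)
  cl <- clusters[genes]
  per <- numeric(0); wt <- numeric(0); unscored <- character(0)
  for (cid in unique(cl)) {
    memb <- genes[cl == cid]
    if (length(memb) < 2) { unscored <- c(unscored, as.character(cid)); next }
    prs <- combn(memb, 2)
    sims <- vapply(seq_len(ncol(prs)), function(k)
      .bma(M, annot[[prs[1, k]]], annot[[prs[2, k]]]), numeric(1))
    per[as.character(cid)] <- mean(sims)
    wt[as.character(cid)] <- length(memb)
  }
  if (!length(per)) stop("no cluster with >= 2 annotated genes")
  list(overall = sum(per * wt) / sum(wt), per_cluster = per,
       weights = wt, unscored = unscored)
}

#' Null distribution of the clustering score under tip relabelling
#'
#' Recomputes the size-weighted score after uniformly random permutations of
#' the gene labels over the fixed cluster structure (the tip-relabel null of
#' the cluster tree): cluster sizes are preserved exactly, only the gene
#' content is shuffled.
#'
#' @inheritParams clustering_score
#' @param n_sets number of random relabellings.
#' @param seed integer seed.
#' @return numeric vector of `n_sets` null overall scores.
#' @export
relabel_null <- function(dag, annot, clusters, n_sets, seed) {
  stopifnot(n_sets >= 1)
  set.seed(as.integer(seed))
  genes <- names(clusters)
  vapply(seq_len(n_sets), function(k) {
    perm <- setNames(clusters[sample(length(clusters))], genes)
    clustering_score(dag, annot, perm)$overall
  }, numeric(1))
}

#' Resampling chi-squared GO enrichment test
#'
#' For each GO term carried by at least `min_freq` annotated genes, computes
#' the Pearson chi-squared statistic of its distribution across clusters,
#' `X^2 = sum over clusters of (O_c - E_c)^2 / E_c` with
#' `E_c = frequency * size_c / N`, where sizes count annotated genes. The
#' chi-squared reference distribution is unreliable here (many clusters have
#' zero expected counts), so the null is estimated by resampling: the
#' annotated genes are randomly reassigned to clusters of the observed sizes
#' `n_resamples` times and `p = (1 + #{null X^2 >= observed}) / (1 +
#' n_resamples)` (the +1 correction never returns an exact zero).
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param clusters named vector gene -> cluster id.
#' @param annot named list gene -> term ids.
#' @param n_resamples number of random reassignments (default 100,000).
#' @param min_freq minimal term frequency (distinct annotated genes carrying
#'   the term directly); default 5 keeps only nonrare terms.
#' @param seed integer seed.
#' @return data.frame with columns `term`, `frequency`, `chi2`, `p`,
#'   `p_adj`, ordered by `p`.
#' @export
enrichment_test <- function(clusters, annot, n_resamples = 1e5,
                            min_freq = 5, seed = 1) {
  stopifnot(n_resamples >= 1, min_freq >= 1)
  genes <- intersect(names(clusters), names(annot))
  genes <- genes[lengths(annot[genes]) > 0]
  if (!length(genes)) stop("no annotated genes in the clustering")
  cl <- as.character(clusters[genes])
  clev <- sort(unique(cl))
  nc <- length(clev)
  sizes <- as.numeric(table(factor(cl, levels = clev)))
  N <- length(genes)

  term_genes <- split(rep(seq_along(genes), lengths(annot[genes])),
                      unlist(annot[genes], use.names = FALSE))
  freq <- lengths(term_genes)
  keep <- freq >= min_freq
  if (!any(keep)) {
    return(data.frame(term = character(), frequency = integer(),
                      chi2 = numeric(), p = numeric(), p_adj = numeric()))
  }
  term_genes <- term_genes[keep]
  freq <- freq[keep]
  tnames <- names(term_genes)
  nt <- length(tnames)

  # term x gene incidence; X^2 = (N / f) * sum_c O_c^2 / n_c - f
  Mi <- matrix(0, nt, N)
  for (k in seq_len(nt)) Mi[k, term_genes[[k]]] <- 1
  zmat <- function(assign_idx) {
    Z <- matrix(0, N, nc)
    Z[cbind(seq_len(N), assign_idx)] <- 1
    Z
  }
  cl_idx <- match(cl, clev)
  chi2_of <- function(O) (N / freq) * as.vector((O * O) %*% (1 / sizes)) - freq
  obs <- chi2_of(Mi %*% zmat(cl_idx))

  set.seed(as.integer(seed))
  exceed <- numeric(nt)
  for (r in seq_len(n_resamples)) {
    stat <- chi2_of(Mi %*% zmat(sample(cl_idx)))
    exceed <- exceed + (stat >= obs - 1e-9)
  }
  p <- (1 + exceed) / (1 + n_resamples)
  out <- data.frame(term = tnames, frequency = as.integer(freq),
                    chi2 = obs, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]; never decreases a p-value and
#' preserves input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Exact binomial overrepresentation test per cluster
#'
#' One-sided exact binomial tail for each cluster: with `k` flagged genes in
#' a cluster of `n` genes and global flagged fraction `p0`,
#' `P(X >= k | n, p0)`. Used to locate clusters enriched in genes with
#' unexpected similarity to a putative lateral-transfer partner (see
#' [flag_unexpected_hits()]).
#'
#' @param clusters named vector gene -> cluster id.
#' @param flagged character vector of flagged gene ids (subset of the
#'   clustered genes).
#' @return data.frame with `cluster`, `n`, `k`, `p`, `p_adj` (BH across
#'   clusters).
#' @export
binomial_overrepresentation <- function(clusters, flagged) {
  genes <- names(clusters)
  if (!all(flagged %in% genes)) stop("flagged genes must be clustered genes")
  p0 <- length(flagged) / length(genes)
  clev <- sort(unique(as.character(clusters)))
  out <- data.frame(cluster = clev, n = NA_integer_, k = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(clev)) {
    memb <- genes[as.character(clusters) == clev[i]]
    n <- length(memb); k <- sum(memb %in% flagged)
    out$n[i] <- n; out$k[i] <- k
    out$p[i] <- if (k == 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$cluster), , drop = FALSE]
}
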