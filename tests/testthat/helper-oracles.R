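# Independent oracles used across the suite. These deliberately avoid the
# package's pruning kernels: transition matrices come from Matrix::expm and
# likelihoods from explicit enumeration over internal-node states.

# brute-force 2-state likelihood: sum over all internal state assignments
enum_loglik2 <- function(tree, x, alpha, beta, prior = c(0.5, 0.5)) {
  Q <- matrix(c(-alpha, alpha, beta, -beta), 2, 2, byrow = TRUE)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  ints <- (ntip + 1):(ntip + po$Nnode)
  Pm <- lapply(po$edge.length, P)
  tot <- 0
  for (comb in 0:(2^length(ints) - 1)) {
    st <- integer(ntip + po$Nnode)
    st[1:ntip] <- x[po$tip.label]
    st[ints] <- as.integer(intToBits(comb))[seq_along(ints)]
    lik <- prior[st[ntip + 1] + 1]
    for (e in seq_len(nrow(po$edge))) {
      lik <- lik * Pm[[e]][st[po$edge[e, 1]] + 1, st[po$edge[e, 2]] + 1]
    }
    tot <- tot + lik
  }
  log(tot)
}

# brute-force 4-state joint likelihood (states (0,0),(0,1),(1,0),(1,1))
enum_loglik4 <- function(tree, x, y, model, prior = rep(0.25, 4)) {
  Q <- coevo::rate_matrix(model)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  ints <- (ntip + 1):(ntip + po$Nnode)
  Pm <- lapply(po$edge.length, P)
  joint <- function(xi, yi) 2L * xi + yi + 1L  # S1..S4 index
  tip_state <- joint(x[po$tip.label], y[po$tip.label])
  nint <- length(ints)
  tot <- 0
  for (comb in 0:(4^nint - 1)) {
    st <- integer(ntip + po$Nnode)
    st[1:ntip] <- tip_state
    c0 <- comb
    for (k in seq_len(nint)) { st[ints[k]] <- c0 %% 4 + 1; c0 <- c0 %/% 4 }
    lik <- prior[st[ntip + 1]]
    for (e in seq_len(nrow(po$edge))) {
      lik <- lik * Pm[[e]][st[po$edge[e, 1]], st[po$edge[e, 2]]]
    }
    tot <- tot + lik
  }
  log(tot)
}

# random non-ultrametric tree with strictly positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expd <- si * sj / choose(n, 2)
  (sij - expd) / ((si + sj) / 2 - expd)
}

# toy ontology: root <- {p, q}; a, b is_a p; c is_a q; s part_of p;
# one obsolete term and one molecular_function term to exercise filtering
toy_obo_path <- function() {
  path <- file.path(tempdir(), "toy.obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: pathway p",
    "namespace: biological_process", "is_a: GO:0008150 ! root", "",
    "[Term]", "id: GO:0000003", "name: process a",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: process b",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000005", "name: branch q",
    "namespace: biological_process", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0000006", "name: process c",
    "namespace: biological_process", "is_a: GO:0000005", "",
    "[Term]", "id: GO:0000008", "name: subunit s",
    "namespace: biological_process",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000007", "name: gone",
    "namespace: biological_process", "is_obsolete: true", "",
    "[Term]", "id: GO:0000010", "name: an activity",
    "namespace: molecular_function"
  ), path)
  path
}

toy_dag <- local({
  dag <- NULL
  function() {
    if (is.null(dag)) dag <<- coevo::parse_obo(toy_obo_path())
    dag
  }
})
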