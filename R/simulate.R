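#' Simulate a birth-death reference tree
#'
#' Wraps [ape::rphylo()] (birth-death process conditioned on the number of
#' tips) and by default rescales the tree to mean root-to-tip depth 1 so
#' that trait rates are expressed in expected events per tree depth. An
#' optional lognormal branch-length jitter (mean 1) breaks the strict clock,
#' which is useful when exercising rooting methods on non-ultrametric trees.
#'
#' @param n_tips number of tips (>= 2); labels are `t1 ... tn`.
#' @param birth,death speciation and extinction rates, `birth > death >= 0`.
#' @param seed integer seed; the tree is deterministic given the seed.
#' @param depth target mean root-to-tip depth (`NULL` to keep the raw
#'   branch lengths).
#' @param jitter_sd standard deviation (log scale) of the multiplicative
#'   branch-length jitter; 0 (default) keeps the tree clock-like.
#' @return a rooted `"phylo"`.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0.5, seed,
                          depth = 1, jitter_sd = 0) {
  stopifnot(n_tips >= 2, birth > death, death >= 0)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  if (jitter_sd > 0) {
    m <- rlnorm(nrow(tree$edge), meanlog = -jitter_sd^2 / 2, sdlog = jitter_sd)
    tree$edge.length <- tree$edge.length * m
  }
  if (!is.null(depth)) {
    d <- mean(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
    if (d > 0) tree$edge.length <- tree$edge.length / d * depth
  }
  tree
}

# exact realisation of a CTMC along one branch: state `s` (1-based index
# into `rates` rows), generator Q, duration t
.evolve_branch <- function(s, Q, t) {
  repeat {
    out <- -Q[s, s]
    if (out <= 0) return(s)
    w <- rexp(1, out)
    if (w >= t) return(s)
    t <- t - w
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(length(probs), 1, prob = probs)
  }
}

# simulate a k-state chain down the tree; returns tip states (1-based)
.simulate_chain <- function(tree, Q, root_state) {
  po <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  state <- integer(nn)
  state[ntip + 1L] <- root_state
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    state[chi] <- .evolve_branch(state[par], Q, po$edge.length[e])
  }
  setNames(state[seq_len(ntip)], po$tip.label)
}

#' Simulate one binary trait on a tree
#'
#' Exact continuous-time realisation (exponential waiting times along each
#' branch) of the 2-state gain/loss chain.
#'
#' @param tree rooted `"phylo"`.
#' @param alpha,beta gain (0 to 1) and loss (1 to 0) rates.
#' @param seed integer seed (omit to continue the current RNG stream).
#' @param root_state 0, 1, or `NULL` to draw from `root_prior`.
#' @param root_prior probabilities of root states (absent, present).
#' @return named 0/1 vector over tips.
#' @export
simulate_trait <- function(tree, alpha, beta, seed = NULL, root_state = NULL,
                           root_prior = c(0.5, 0.5)) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  Q <- matrix(c(-alpha, alpha, beta, -beta), 2, 2, byrow = TRUE)
  if (is.null(root_state)) root_state <- sample(0:1, 1, prob = root_prior)
  st <- .simulate_chain(tree, Q, as.integer(root_state) + 1L)
  st - 1L
}

#' Simulate a pair of binary traits
#'
#' Under an [independent_model()] the two traits are simulated as separate
#' 2-state chains; under a [dependent_model()] a single 4-state joint chain
#' over (X, Y) is realised and decoded.
#'
#' @param tree rooted `"phylo"`.
#' @param model an `independent_model` or `dependent_model`.
#' @param root_prior `"uniform"` or `"stationary"`, matching the likelihood's
#'   assumption about the root.
#' @param seed integer seed.
#' @return list with named 0/1 vectors `x` and `y`.
#' @export
simulate_pair <- function(tree, model, root_prior = "uniform", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (inherits(model, "independent_model")) {
    r <- model$rates
    x <- simulate_trait(tree, r["alpha1"], r["beta1"],
                        root_prior = .root_prior2(root_prior, r["alpha1"], r["beta1"]))
    y <- simulate_trait(tree, r["alpha2"], r["beta2"],
                        root_prior = .root_prior2(root_prior, r["alpha2"], r["beta2"]))
    return(list(x = x, y = y))
  }
  stopifnot(inherits(model, "dependent_model"))
  Q <- rate_matrix(model)
  prior <- if (identical(root_prior, "stationary")) .stationary4(Q) else rep(0.25, 4)
  root <- sample.int(4, 1, prob = prior)
  st <- .simulate_chain(tree, Q, root)
  # S1=(0,0) S2=(0,1) S3=(1,0) S4=(1,1)
  list(x = as.integer(st %in% c(3, 4)) |> setNames(names(st)),
       y = as.integer(st %in% c(2, 4)) |> setNames(names(st)))
}

.root_prior2 <- function(root_prior, alpha, beta) {
  if (identical(root_prior, "stationary")) .stationary2(alpha, beta)
  else c(0.5, 0.5)
}

#' Simulate a profile set with correlated blocks
#'
#' Validation harness for the whole pipeline (this latent-block construction
#' is a property of the test harness, not of the correlated-evolution
#' method itself). Each block has one latent "pathway presence" trait
#' simulated under the 2-state chain; block members copy the latent trait
#' with independent per-tip noise flips at probability `noise`. Profiles
#' outside any block are independent 2-state chains. Constant columns carry
#' no signal for the pairwise test, so by default any constant draw is
#' redrawn (within the same seeded RNG stream, keeping the output
#' deterministic given the seed).
#'
#' @param tree rooted `"phylo"`.
#' @param n_profiles total number of profiles (columns).
#' @param blocks integer vector of block sizes (e.g. `c(5, 5)`); their sum
#'   must not exceed `n_profiles`.
#' @param noise per-tip flip probability applied to block members.
#' @param alpha,beta gain/loss rates of latent and independent traits, in
#'   events per unit tree depth.
#' @param seed integer seed (mandatory).
#' @param ensure_informative redraw constant columns (and constant latent
#'   traits)?
#' @param max_redraws redraw budget per column before giving up with a
#'   warning.
#' @return a [profile_matrix()]; attribute `blocks` is an integer vector of
#'   block labels per column (0 = independent background).
#' @export
simulate_profile_set <- function(tree, n_profiles = 20, blocks = c(5, 5),
                                 noise = 0.05, alpha = 1, beta = 1, seed,
                                 ensure_informative = TRUE, max_redraws = 50) {
  stopifnot(sum(blocks) <= n_profiles, noise >= 0, noise <= 0.5)
  set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  draw_trait <- function() {
    for (k in seq_len(max_redraws)) {
      tr <- simulate_trait(tree, alpha, beta)
      if (!ensure_informative || (sum(tr) > 0 && sum(tr) < ntip)) return(tr)
    }
    warning("constant trait persisted after ", max_redraws, " redraws")
    tr
  }
  apply_noise <- function(latent) {
    for (k in seq_len(max_redraws)) {
      flips <- runif(ntip) < noise
      prof <- as.integer(xor(latent == 1L, flips))
      if (!ensure_informative || (sum(prof) > 0 && sum(prof) < ntip))
        return(setNames(prof, names(latent)))
    }
    warning("constant profile persisted after ", max_redraws, " redraws")
    setNames(prof, names(latent))
  }
  cols <- list(); labels <- integer(0)
  for (b in seq_along(blocks)) {
    latent <- draw_trait()
    for (m in seq_len(blocks[b])) {
      cols[[length(cols) + 1L]] <- apply_noise(latent)
      labels <- c(labels, b)
    }
  }
  for (m in seq_len(n_profiles - sum(blocks))) {
    cols[[length(cols) + 1L]] <- draw_trait()
    labels <- c(labels, 0L)
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- sprintf("prof%03d", seq_len(ncol(mat)))
  rownames(mat) <- tree$tip.label
  pm <- profile_matrix(mat)
  attr(pm, "blocks") <- setNames(labels, colnames(mat))
  pm
}
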