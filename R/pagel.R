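#' Model constructors for the correlated-evolution test
#'
#' `independent_model()` holds the four rates of two binary characters
#' evolving independently (gain/loss for each trait); `dependent_model()`
#' holds the eight transition rates of the joint four-state chain over
#' ordered states S1=(0,0), S2=(0,1), S3=(1,0), S4=(1,1), with simultaneous
#' dual transitions fixed at zero. The difference in free parameters, 8 - 4 =
#' 4, is the degrees of freedom of the likelihood-ratio test.
#'
#' @param alpha1,beta1 gain (0 to 1) and loss (1 to 0) rates of trait X.
#' @param alpha2,beta2 same for trait Y.
#' @return object of class `"independent_model"`.
#' @export
independent_model <- function(alpha1, beta1, alpha2, beta2) {
  r <- setNames(as.numeric(c(alpha1, beta1, alpha2, beta2)),
                c("alpha1", "beta1", "alpha2", "beta2"))
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  structure(list(rates = r), class = "independent_model")
}

#' @rdname independent_model
#' @param q12,q13,q21,q24,q31,q34,q42,q43 transition rates between the joint
#'   states, indexed source-target (e.g. `q13` is the S1=(0,0) to S3=(1,0)
#'   gain of X while Y is absent).
#' @export
dependent_model <- function(q12, q13, q21, q24, q31, q34, q42, q43) {
  r <- setNames(as.numeric(c(q12, q13, q21, q24, q31, q34, q42, q43)),
                c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43"))
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  structure(list(rates = r), class = "dependent_model")
}

#' @rdname independent_model
#' @param model an `independent_model`.
#' @return `as_dependent()`: the dependent model whose joint chain factorises
#'   into the two independent chains (the nesting embedding).
#' @export
as_dependent <- function(model) {
  r <- model$rates
  dependent_model(q12 = r["alpha2"], q13 = r["alpha1"],
                  q21 = r["beta2"],  q24 = r["alpha1"],
                  q31 = r["beta1"],  q34 = r["alpha2"],
                  q42 = r["beta1"],  q43 = r["beta2"])
}

#' @rdname independent_model
#' @export
n_free_params <- function(model) {
  if (inherits(model, "independent_model")) return(4L)
  if (inherits(model, "dependent_model")) return(8L)
  stop("unknown model class")
}

#' @rdname independent_model
#' @return `rate_matrix()`: the 4x4 generator of a dependent model (rows
#'   summing to zero, forbidden dual transitions exactly zero).
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "dependent_model"))
  q <- model$rates
  Q <- matrix(0, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  Q[1, 2] <- q["q12"]; Q[1, 3] <- q["q13"]
  Q[2, 1] <- q["q21"]; Q[2, 4] <- q["q24"]
  Q[3, 1] <- q["q31"]; Q[3, 4] <- q["q34"]
  Q[4, 2] <- q["q42"]; Q[4, 3] <- q["q43"]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Fitting options for the Pagel likelihood machinery
#'
#' @param restarts number of random restarts of the bounded optimiser, drawn
#'   log-uniformly over the rate bounds (the dependent fit additionally
#'   starts from the fitted independent model, which guarantees the nesting
#'   inequality up to optimiser improvement).
#' @param seed integer seed for restart draws.
#' @param root_prior `"uniform"` (default; equal weight on root states) or
#'   `"stationary"` (stationary law of the fitted generator).
#' @param rate_bounds lower/upper bounds on rates, applied after rescaling
#'   the tree to mean root-to-tip depth 1 (the LR statistic is invariant to
#'   this joint rescaling of rates and branch lengths).
#' @param maxit maximal L-BFGS-B iterations per restart.
#' @param zero_floor branch lengths are floored at this value inside the
#'   likelihood only, to avoid degenerate transition matrices.
#' @param neg_tol negative LR excursions smaller than this are clamped to 0;
#'   larger ones trigger a refit with `refit_factor` times the restarts.
#' @param refit_factor multiplier on restarts for the refit pass.
#' @return list of options for [lrt_pair()] and friends.
#' @export
pagel_options <- function(restarts = 10L, seed = 1L,
                          root_prior = c("uniform", "stationary"),
                          rate_bounds = c(1e-7, 1e3), maxit = 200L,
                          zero_floor = 1e-9, neg_tol = 1e-3,
                          refit_factor = 5L) {
  list(restarts = as.integer(restarts), seed = as.integer(seed),
       root_prior = match.arg(root_prior),
       rate_bounds = rate_bounds, maxit = as.integer(maxit),
       zero_floor = zero_floor, neg_tol = neg_tol,
       refit_factor = as.integer(refit_factor))
}

# postorder edge representation consumed by the C++ pruning kernels
.prep_tree <- function(tree, rescale = FALSE) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  depth <- ape::node.depth.edgelength(po)[seq_len(ntip)]
  scale <- 1
  el <- po$edge.length
  if (rescale) {
    md <- mean(depth)
    if (md > 0) { scale <- 1 / md; el <- el * scale }
  }
  list(edge = po$edge, elen = el, ntip = ntip, nnode = po$Nnode,
       tips = po$tip.label, scale = scale)
}

# map a tip-state vector (named or positional, values 0/1/NA) to the
# integer coding used by the kernels (-1 = missing)
.tip_states <- function(x, tips) {
  if (!is.null(names(x))) {
    missing <- setdiff(tips, names(x))
    if (length(missing)) stop("no state for tip(s): ",
                              paste(missing, collapse = ", "))
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop("state vector length does not match the number of tips")
  }
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) stop("tip states must be 0, 1 or NA")
  x[is.na(x)] <- -1L
  x
}

.stationary2 <- function(alpha, beta) {
  s <- alpha + beta
  if (s <= 0) return(c(0.5, 0.5))
  c(beta, alpha) / s
}

.stationary4 <- function(Q) {
  A <- rbind(t(Q), rep(1, 4))
  b <- c(0, 0, 0, 0, 1)
  pi <- tryCatch(as.vector(qr.solve(A, b)), error = function(e) rep(0.25, 4))
  pi[pi < 0] <- 0
  if (sum(pi) <= 0) return(rep(0.25, 4))
  pi / sum(pi)
}

#' Pruning log-likelihood of one binary trait
#'
#' Computes the log-likelihood of tip presence/absence data under a 2-state
#' continuous-time Markov chain with gain rate `alpha` and loss rate `beta`,
#' by Felsenstein's pruning algorithm with closed-form transition
#' probabilities. `NA` tip states are treated as ambiguous.
#'
#' @param tree a rooted `"phylo"`.
#' @param x tip states (0/1/NA), named by tip label or in tip order.
#' @param alpha,beta gain and loss rates (>= 0).
#' @param root_prior `"uniform"` or `"stationary"`.
#' @param zero_floor branch-length floor used inside the likelihood.
#' @return the log-likelihood.
#' @export
loglik_single_trait <- function(tree, x, alpha, beta,
                                root_prior = "uniform", zero_floor = 1e-9) {
  if (any(!is.finite(c(alpha, beta))) || alpha < 0 || beta < 0)
    stop("rates must be finite and >= 0")
  tp <- .prep_tree(tree)
  xs <- .tip_states(x, tp$tips)
  prior <- if (identical(root_prior, "stationary")) .stationary2(alpha, beta)
           else c(0.5, 0.5)
  loglik2_cpp(tp$edge, tp$elen, tp$ntip, tp$nnode, xs, alpha, beta,
              prior, zero_floor)
}

#' Pruning log-likelihood of two binary traits under the dependent model
#'
#' Joint 4-state chain over (X, Y) with the eight free rates of
#' [dependent_model()]; transition matrices come from an eigendecomposition
#' of the generator (with a scaling-and-squaring fallback).
#'
#' @inheritParams loglik_single_trait
#' @param y second trait's tip states.
#' @param model a [dependent_model()].
#' @return the log-likelihood.
#' @export
loglik_dependent <- function(tree, x, y, model, root_prior = "uniform",
                             zero_floor = 1e-9) {
  stopifnot(inherits(model, "dependent_model"))
  tp <- .prep_tree(tree)
  xs <- .tip_states(x, tp$tips)
  ys <- .tip_states(y, tp$tips)
  prior <- if (identical(root_prior, "stationary"))
    .stationary4(rate_matrix(model)) else rep(0.25, 4)
  loglik4_cpp(tp$edge, tp$elen, tp$ntip, tp$nnode, xs, ys,
              unname(model$rates), prior, zero_floor)
}

# ---- internal fitting machinery (operates on a prepped, rescaled tree) ----

.nll2 <- function(logpar, tp, xs, root_prior, floor) {
  a <- exp(logpar[1]); b <- exp(logpar[2])
  prior <- if (identical(root_prior, "stationary")) .stationary2(a, b)
           else c(0.5, 0.5)
  -loglik2_cpp(tp$edge, tp$elen, tp$ntip, tp$nnode, xs, a, b, prior, floor)
}

.nll4 <- function(logpar, tp, xs, ys, root_prior, floor) {
  q <- exp(logpar)
  prior <- if (identical(root_prior, "stationary")) {
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- q[1]; Q[1, 3] <- q[2]; Q[2, 1] <- q[3]; Q[2, 4] <- q[4]
    Q[3, 1] <- q[5]; Q[3, 4] <- q[6]; Q[4, 2] <- q[7]; Q[4, 3] <- q[8]
    diag(Q) <- -rowSums(Q)
    .stationary4(Q)
  } else rep(0.25, 4)
  -loglik4_cpp(tp$edge, tp$elen, tp$ntip, tp$nnode, xs, ys, q, prior, floor)
}

.multistart_optim <- function(fn, npar, starts_extra, opts, n_restarts) {
  lb <- log(opts$rate_bounds[1]); ub <- log(opts$rate_bounds[2])
  starts <- starts_extra
  if (n_restarts > 0) {
    rnd <- matrix(runif(n_restarts * npar, log(1e-2), log(1e2)), n_restarts, npar)
    starts <- rbind(starts, rnd)
  }
  best <- NULL
  conv_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[i, ], lb), ub), fn, method = "L-BFGS-B",
            lower = lb, upper = ub,
            control = list(maxit = opts$maxit, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence != 0) conv_fail <- conv_fail + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimiser starts failed")
  rates <- exp(best$par)
  boundary <- any(rates <= opts$rate_bounds[1] * 1.01) ||
    any(rates >= opts$rate_bounds[2] * 0.99)
  list(rates = rates, nll = best$value, boundary = boundary,
       restarts = nrow(starts), conv_fail = conv_fail)
}

.fit_trait2 <- function(tp, xs, opts) {
  fn <- function(p) .nll2(p, tp, xs, opts$root_prior, opts$zero_floor)
  .multistart_optim(fn, 2L, matrix(0, 1, 2), opts, opts$restarts)
}

#' Fit the independent model by maximum likelihood
#'
#' The independent model factorises over the two traits, so each trait's
#' gain/loss pair is fitted separately by bounded multi-start optimisation in
#' log-rate space. The tree is rescaled internally to mean root-to-tip depth
#' 1; reported rates are on the original branch-length scale and the
#' log-likelihood is invariant to the rescaling.
#'
#' @inheritParams loglik_dependent
#' @param options a [pagel_options()] list.
#' @return list with `model` ([independent_model()]), `loglik`, and fitting
#'   diagnostics (`boundary`, `restarts`, `conv_fail`).
#' @export
fit_independent <- function(tree, x, y, options = pagel_options()) {
  tp <- .prep_tree(tree, rescale = TRUE)
  xs <- .tip_states(x, tp$tips); ys <- .tip_states(y, tp$tips)
  set.seed(options$seed)
  fx <- .fit_trait2(tp, xs, options)
  fy <- .fit_trait2(tp, ys, options)
  model <- independent_model(alpha1 = fx$rates[1] * tp$scale,
                             beta1  = fx$rates[2] * tp$scale,
                             alpha2 = fy$rates[1] * tp$scale,
                             beta2  = fy$rates[2] * tp$scale)
  list(model = model, loglik = -(fx$nll + fy$nll),
       boundary = fx$boundary || fy$boundary,
       restarts = fx$restarts + fy$restarts,
       conv_fail = fx$conv_fail + fy$conv_fail,
       scale = tp$scale,
       rates_scaled = c(fx$rates, fy$rates))
}

#' Fit the dependent model by maximum likelihood
#'
#' Eight-rate joint chain fitted by bounded multi-start optimisation in
#' log-rate space. In addition to `options$restarts` random starts, the
#' optimiser always starts from the independence-structured point implied by
#' `init` (a fitted independent model, when supplied), which makes the
#' nesting inequality `lnL_dep >= lnL_indep` hold up to optimiser tolerance.
#'
#' @inheritParams fit_independent
#' @param init optional result of [fit_independent()] used as a warm start.
#' @return list with `model` ([dependent_model()]), `loglik`, diagnostics.
#' @export
fit_dependent <- function(tree, x, y, options = pagel_options(), init = NULL) {
  tp <- .prep_tree(tree, rescale = TRUE)
  xs <- .tip_states(x, tp$tips); ys <- .tip_states(y, tp$tips)
  fn <- function(p) .nll4(p, tp, xs, ys, options$root_prior, options$zero_floor)
  starts <- matrix(log(rep(1, 8)), 1, 8)
  if (!is.null(init)) {
    dep0 <- as_dependent(init$model)
    starts <- rbind(log(pmax(unname(dep0$rates) / tp$scale,
                             options$rate_bounds[1])), starts)
  }
  set.seed(options$seed + 1L)
  fit <- .multistart_optim(fn, 8L, starts, options, options$restarts)
  q <- fit$rates * tp$scale
  model <- dependent_model(q[1], q[2], q[3], q[4], q[5], q[6], q[7], q[8])
  list(model = model, loglik = -fit$nll, boundary = fit$boundary,
       restarts = fit$restarts, conv_fail = fit$conv_fail, scale = tp$scale)
}

#' Likelihood-ratio test of correlated evolution for one profile pair
#'
#' Fits the 4-parameter independent and 8-parameter dependent models and
#' returns `LR = 2 (lnL_dep - lnL_indep)`, clamped at zero when optimiser
#' noise produces a small negative excursion (excursions beyond
#' `options$neg_tol` trigger a refit with more restarts, and are flagged if
#' they persist). A reference p-value from the chi-squared distribution with
#' 4 degrees of freedom (the difference in free parameters) is included.
#'
#' @inheritParams fit_independent
#' @return object of class `"pagel_pair"`: a list with `lnL_indep`,
#'   `lnL_dep`, `LR`, `df`, `p_value`, both fitted models and flags.
#' @export
lrt_pair <- function(tree, x, y, options = pagel_options()) {
  fi <- fit_independent(tree, x, y, options)
  fd <- fit_dependent(tree, x, y, options, init = fi)
  lr <- 2 * (fd$loglik - fi$loglik)
  flag <- character()
  if (lr < 0) {
    if (lr < -options$neg_tol) {
      opts2 <- options
      opts2$restarts <- options$restarts * options$refit_factor
      opts2$seed <- options$seed + 7L
      fd2 <- fit_dependent(tree, x, y, opts2, init = fi)
      if (fd2$loglik > fd$loglik) fd <- fd2
      lr <- 2 * (fd$loglik - fi$loglik)
      if (lr < -options$neg_tol) flag <- c(flag, "negative_lr")
    }
    lr <- max(lr, 0)
  }
  if (fi$boundary || fd$boundary) flag <- c(flag, "boundary")
  if (fi$conv_fail + fd$conv_fail > 0) flag <- c(flag, "nonconvergence")
  structure(list(lnL_indep = fi$loglik, lnL_dep = fd$loglik,
                 LR = lr, df = 4L,
                 p_value = pchisq(lr, df = 4, lower.tail = FALSE),
                 independent = fi$model, dependent = fd$model,
                 flags = flag),
            class = "pagel_pair")
}

#' @export
print.pagel_pair <- function(x, ...) {
  cat(sprintf("Pagel LRT: lnL_indep = %.4f, lnL_dep = %.4f, LR = %.4f (df = %d, p = %.3g)\n",
              x$lnL_indep, x$lnL_dep, x$LR, x$df, x$p_value))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# deterministic per-pair seed, independent of chunking or evaluation order
.pair_seed <- function(seed, i, j) {
  as.integer((as.double(seed) * 1000003 + i * 7919 + j * 104729) %% 2147483647)
}

#' Likelihood-ratio statistics for all profile pairs
#'
#' Computes the symmetric LR matrix over all unordered pairs of distinct,
#' informative profiles. Each pair uses a seed derived deterministically from
#' `options$seed` and the pair indices, so results are identical however the
#' pair list is chunked. Completed pairs can be checkpointed to a TSV and
#' are skipped on resume. The diagonal is set to the maximum off-diagonal LR
#' so that the self-distance becomes zero after the distance transform.
#'
#' @param pm a deduplicated [profile_matrix()]; constant (uninformative)
#'   profiles are dropped with a message and recorded in the
#'   `"dropped_constant"` attribute of the result.
#' @param tree rooted `"phylo"` covering the matrix genomes.
#' @param options a [pagel_options()] list.
#' @param checkpoint optional TSV path; completed pairs are appended and
#'   reused on resume.
#' @param pairs optional two-column integer matrix restricting computation to
#'   a subset of pairs (for manual parallel chunking); the returned matrix
#'   then contains `NA` for unprocessed pairs.
#' @return symmetric numeric LR matrix with profile ids as dimnames.
#' @export
all_pairs_lrt <- function(pm, tree, options = pagel_options(),
                          checkpoint = NULL, pairs = NULL) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!all(rownames(pm$mat) %in% tree$tip.label))
    stop("tree tips must cover matrix genomes")
  info <- informative_profiles(pm)
  dropped <- names(info)[!info]
  if (length(dropped)) {
    message(length(dropped), " constant profile(s) excluded from pairwise testing")
  }
  mat <- pm$mat[, info, drop = FALSE]
  ids <- colnames(mat)
  p <- length(ids)
  if (p < 2) stop("need at least two informative profiles")
  all_pairs <- t(combn(p, 2))
  if (is.null(pairs)) pairs <- all_pairs

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.table(checkpoint, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  }
  lr <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  if (!is.null(done) && nrow(done)) {
    ok <- done$id_i %in% ids & done$id_j %in% ids
    done <- done[ok, , drop = FALSE]
    lr[cbind(done$id_i, done$id_j)] <- done$LR
    lr[cbind(done$id_j, done$id_i)] <- done$LR
  }
  con <- NULL
  if (!is.null(checkpoint)) {
    new_file <- !file.exists(checkpoint)
    con <- file(checkpoint, "a")
    on.exit(close(con))
    if (new_file)
      writeLines("i\tj\tid_i\tid_j\tlnL_indep\tlnL_dep\tLR\tflags", con)
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!is.na(lr[i, j])) next
    opts <- options
    opts$seed <- .pair_seed(options$seed, i, j)
    res <- lrt_pair(tree, mat[, i], mat[, j], opts)
    lr[i, j] <- lr[j, i] <- res$LR
    if (!is.null(con)) {
      writeLines(sprintf("%d\t%d\t%s\t%s\t%.17g\t%.17g\t%.17g\t%s",
                         i, j, ids[i], ids[j], res$lnL_indep, res$lnL_dep,
                         res$LR, paste(res$flags, collapse = ";")), con)
      flush(con)
    }
  }
  off <- lr[upper.tri(lr)]
  diag(lr) <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  attr(lr, "dropped_constant") <- dropped
  lr
}
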