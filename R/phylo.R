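#' Read and validate a rooted newick tree
#'
#' Parses a newick string or file into an `ape` `"phylo"` tree and checks
#' the properties the reconstruction requires: unique tip labels, branch
#' lengths present on every edge, and no negative lengths. Polytomies are
#' allowed.
#'
#' @param x A newick string, or the path of a file containing one.
#' @return A `"phylo"` object.
#' @examples
#' read_newick("((A:1,B:1):0.5,C:1.5);")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  tr <- tryCatch({
    if (file.exists(x) && !grepl("\\(", x)) {
      ape::read.tree(x)
    } else {
      ape::read.tree(text = x)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick input")
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("every branch must carry a length")
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  tr
}

#' Transition probabilities of the equal-rates two-state chain
#'
#' Closed-form transition matrix of the continuous-time Markov chain with a
#' single rate `q` in both directions over a branch of length `t`:
#' \eqn{P(stay) = (1 + e^{-2qt})/2}, \eqn{P(switch) = (1 - e^{-2qt})/2}.
#'
#' @param q Transition rate (per unit branch length), non-negative.
#' @param t Branch length, non-negative.
#' @return A 2x2 stochastic matrix (rows: current state 0/1).
#' @export
transition_probability <- function(q, t) {
  stopifnot(is.numeric(q), is.numeric(t), length(q) == 1L, length(t) == 1L,
            is.finite(q), is.finite(t))
  if (q < 0 || t < 0) stop("rate and branch length must be non-negative")
  stay <- (1 + exp(-2 * q * t)) / 2
  sw <- 1 - stay
  matrix(c(stay, sw, sw, stay), nrow = 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Normalise a tip-state specification into an integer vector of 0/1 named
# by tip label, covering every tip of the tree.
check_states <- function(tree, states) {
  if (is.data.frame(states)) {
    states <- stats::setNames(states[[2L]], as.character(states[[1L]]))
  }
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("missing state for tip(s): ", paste(miss, collapse = ", "))
  }
  s <- as.integer(states[tree$tip.label])
  if (anyNA(s) || !all(s %in% c(0L, 1L))) stop("states must be 0 or 1")
  stats::setNames(s, tree$tip.label)
}

# Post-order (downward) partial likelihoods with per-node log scaling.
# Returns list(partial = matrix n_nodes x 2, logscale = vector, root = id).
prune_partials <- function(tree, states, q) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  L <- matrix(1, nnode, 2)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), states[tr$tip.label] + 1L)] <- 1
  logsc <- numeric(nnode)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    P <- transition_probability(q, tr$edge.length[e])
    v <- as.vector(P %*% L[child, ])
    L[parent, ] <- L[parent, ] * v
    logsc[parent] <- logsc[parent] + logsc[child]
    mx <- max(L[parent, ])
    if (mx > 0 && mx < 1e-100) {
      L[parent, ] <- L[parent, ] / mx
      logsc[parent] <- logsc[parent] + log(mx)
    }
  }
  root <- ntip + 1L
  list(partial = L, logscale = logsc, root = root, tree = tr, ntip = ntip)
}

#' Log-likelihood of tip states under the equal-rates model
#'
#' Exact tree likelihood of binary tip states under the single-rate
#' two-state Markov chain, computed by post-order pruning with a uniform
#' (1/2, 1/2) root prior — the stationary distribution of the symmetric
#' chain. Returns `-Inf` for configurations impossible at the given rate
#' (e.g. differing tip states at `q = 0`).
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @param states Tip states: named 0/1 vector or a two-column
#'   (label, state) data frame covering every tip.
#' @param q Transition rate, non-negative.
#' @return The log-likelihood.
#' @export
er_loglik <- function(tree, states, q) {
  stopifnot(inherits(tree, "phylo"), is.numeric(q), length(q) == 1L, q >= 0)
  states <- check_states(tree, states)
  pr <- prune_partials(tree, states, q)
  lik <- sum(0.5 * pr$partial[pr$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

#' Maximum-likelihood transition rate
#'
#' Fits the single transition rate of the equal-rates model by bounded
#' one-dimensional maximisation of [er_loglik()] (golden-section/parabolic
#' search on the log-rate scale, relative precision about 1e-7). When all
#' tips share one state the likelihood is maximised at the lower bound and
#' the fit is flagged as a boundary solution.
#'
#' @inheritParams er_loglik
#' @param bounds Search interval for the rate; defaults to
#'   `c(1e-8, 100/tree height)`.
#' @return An object of class `"er_fit"`: list with `rate`, `loglik`,
#'   `boundary` flag and the search `bounds`.
#' @export
fit_er_rate <- function(tree, states, bounds = NULL) {
  stopifnot(inherits(tree, "phylo"))
  states <- check_states(tree, states)
  if (is.null(bounds)) {
    height <- max(ape::node.depth.edgelength(tree))
    if (height <= 0) stop("tree has zero height")
    bounds <- c(1e-8, 100 / height)
  }
  stopifnot(length(bounds) == 2L, bounds[1L] > 0, bounds[2L] > bounds[1L])
  f <- function(lq) er_loglik(tree, states, exp(lq))
  opt <- stats::optimize(f, interval = log(bounds), maximum = TRUE,
                         tol = 1e-8)
  cand <- c(exp(opt$maximum), bounds)
  ll <- c(opt$objective, f(log(bounds[1L])), f(log(bounds[2L])))
  i <- which.max(ll)
  structure(
    list(rate = cand[i], loglik = ll[i],
         boundary = i > 1L ||
           exp(opt$maximum) / bounds[1L] < 1.001 ||
           bounds[2L] / exp(opt$maximum) < 1.001,
         bounds = bounds),
    class = "er_fit"
  )
}

#' @export
print.er_fit <- function(x, digits = 5, ...) {
  cat("Equal-rates two-state Markov fit\n")
  cat("  rate q-hat:     ", format(x$rate, digits = digits),
      if (x$boundary) " (boundary of search interval)", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Marginal ancestral-state probabilities
#'
#' For each internal node, the marginal posterior probability of each
#' state given the tip data and the transition rate ("proportional
#' probabilities"), under the uniform root prior. Computed by combining
#' downward (pruning) partial likelihoods with upward partials propagated
#' from the root — equivalent to re-rooting the tree at each node.
#'
#' @inheritParams er_loglik
#' @param q Transition rate, or a fitted [fit_er_rate()] object.
#' @return An object of class `"ancestral_reconstruction"`: a data frame
#'   with one row per internal node (`node`, `prob_absent`,
#'   `prob_present`), with the rate and log-likelihood as attributes.
#' @export
ancestral_marginals <- function(tree, states, q) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(q, "er_fit")) q <- q$rate
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0)
  states <- check_states(tree, states)
  ll <- er_loglik(tree, states, q)
  if (!is.finite(ll)) {
    stop("tip states have zero likelihood at this rate; marginals undefined")
  }
  pr <- prune_partials(tree, states, q)
  tr <- pr$tree
  ntip <- pr$ntip
  nnode <- ntip + tr$Nnode
  D <- pr$partial
  # Upward partials: U[v, s] is the likelihood of everything outside the
  # clade of v given state s at v, including the root prior.
  U <- matrix(NA_real_, nnode, 2)
  U[pr$root, ] <- 0.5
  edges <- rev(seq_len(nrow(tr$edge)))  # preorder: parents before children
  # Pre-compute each edge's lifted child partial v_e(s_parent).
  lifted <- matrix(0, nrow(tr$edge), 2)
  for (e in seq_len(nrow(tr$edge))) {
    P <- transition_probability(q, tr$edge.length[e])
    lifted[e, ] <- as.vector(P %*% D[tr$edge[e, 2L], ])
  }
  for (e in edges) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    sib <- which(tr$edge[, 1L] == parent)
    sib <- sib[sib != e]
    w <- U[parent, ]
    for (s in sib) w <- w * lifted[s, ]
    P <- transition_probability(q, tr$edge.length[e])
    U[child, ] <- as.vector(t(P) %*% w)
    mx <- max(U[child, ])
    if (mx > 0) U[child, ] <- U[child, ] / mx
  }
  internal <- (ntip + 1L):nnode
  marg <- D[internal, , drop = FALSE] * U[internal, , drop = FALSE]
  marg <- marg / rowSums(marg)
  structure(
    data.frame(node = internal, prob_absent = marg[, 1L],
               prob_present = marg[, 2L]),
    class = c("ancestral_reconstruction", "data.frame"),
    rate = q, loglik = ll, tree = tr
  )
}

#' @export
print.ancestral_reconstruction <- function(x, digits = 3, ...) {
  cat("Ancestral reconstruction of post-reproductive lifespans\n")
  cat("  equal-rates model, q = ", format(attr(x, "rate"), digits = digits),
      ", logL = ", format(attr(x, "loglik"), digits = digits), "\n", sep = "")
  cat("  proportional probability of presence at internal nodes:\n")
  print(data.frame(node = x$node,
                   prob_present = round(x$prob_present, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Simulate binary trait evolution on a tree
#'
#' Evolves a 0/1 trait along a phylogeny under the equal-rates chain from
#' a root state drawn from the stationary (1/2, 1/2) distribution. Used to
#' validate rate recovery by [fit_er_rate()].
#'
#' @inheritParams er_loglik
#' @param q Generating transition rate.
#' @param seed Optional integer seed.
#' @return Named 0/1 vector of tip states.
#' @export
simulate_er_states <- function(tree, q, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), is.numeric(q), q >= 0)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  with_seed(seed, {
    state <- integer(nnode)
    root <- ntip + 1L
    state[root] <- stats::rbinom(1L, 1L, 0.5)
    for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
      parent <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      p_switch <- (1 - exp(-2 * q * tr$edge.length[e])) / 2
      flip <- stats::rbinom(1L, 1L, p_switch)
      state[child] <- if (flip) 1L - state[parent] else state[parent]
    }
    stats::setNames(state[seq_len(ntip)], tr$tip.label)
  })
}
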