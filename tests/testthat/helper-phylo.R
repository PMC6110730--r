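# Enumeration oracles for the two-state equal-rates model: sum the
# probability of every assignment of states to internal nodes. Exponential
# in the node count, usable only on small trees; entirely independent of
# the pruning implementation.

enum_joint <- function(tree, states, q) {
  states <- physprr:::check_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  full <- integer(nnode)
  full[seq_len(ntip)] <- states[tree$tip.label]
  probs <- apply(grid, 1, function(assign) {
    full[internal] <- assign
    p <- 0.5  # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_probability(q, tree$edge.length[e])
      p <- p * P[full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
    }
    p
  })
  list(lik = sum(probs), grid = grid, probs = probs, internal = internal)
}

enum_loglik <- function(tree, states, q) {
  lik <- enum_joint(tree, states, q)$lik
  if (lik <= 0) -Inf else log(lik)
}

enum_marginals <- function(tree, states, q) {
  ej <- enum_joint(tree, states, q)
  t(vapply(seq_along(ej$internal), function(i) {
    p1 <- sum(ej$probs[ej$grid[, i] == 1])
    c(p0 = 1 - p1 / ej$lik, p1 = p1 / ej$lik)
  }, numeric(2)))
}

random_small_tree <- function(ntips) {
  tr <- ape::rtree(ntips, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

balanced_tree_64 <- function() {
  tr <- ape::stree(64, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
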