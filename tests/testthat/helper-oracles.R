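# Independent oracles for the test suite: brute-force full-joint
# enumeration (no variable elimination), brute-force mutual information,
# finite-difference sensitivity, and a seeded random-network generator.

# random acyclic network: <= max_nodes nodes, 2..max_states states each,
# Dirichlet(1) CPT columns
random_bbn <- function(seed, max_nodes = 8, max_states = 4) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  nms <- paste0("N", seq_len(n))
  nodes <- lapply(seq_len(n), function(i) {
    k <- sample(2:max_states, 1)
    paste0("s", seq_len(k))
  })
  names(nodes) <- nms
  arcs <- matrix(character(0), ncol = 2)
  for (j in 2:n) for (i in 1:(j - 1))
    if (runif(1) < 0.4) arcs <- rbind(arcs, c(nms[i], nms[j]))
  colnames(arcs) <- c("parent", "child")
  cpts <- lapply(nms, function(nm) {
    parents <- arcs[arcs[, "child"] == nm, "parent"]
    card <- c(length(nodes[[nm]]), vapply(parents, function(p)
      length(nodes[[p]]), integer(1)))
    ncols <- prod(card[-1])
    cols <- matrix(rgamma(card[1] * max(ncols, 1), 1), nrow = card[1])
    cols <- sweep(cols, 2, colSums(cols), `/`)
    list(parents = unname(parents), prob = array(cols, dim = card))
  })
  names(cpts) <- nms
  bbn(nodes = nodes, arcs = arcs, cpts = cpts)
}

# full-joint enumeration: every outcome and its probability, computed by
# direct CPT-entry products (no inference machinery)
oracle_joint <- function(net) {
  states <- lapply(net$nodes, function(nd) nd$states)
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (nm in names(states)) {
    ct <- net$cpts[[nm]]
    card <- dim(ct$prob)
    assn <- cbind(match(grid[[nm]], states[[nm]]))
    for (pa in ct$parents) assn <- cbind(assn, match(grid[[pa]], states[[pa]]))
    stride <- cumprod(c(1, card[-length(card)]))
    idx <- as.integer((assn - 1) %*% stride) + 1L
    p <- p * as.vector(ct$prob)[idx]
  }
  list(grid = grid, p = p, states = states)
}

# posterior of one node by summing the enumerated joint
oracle_posterior <- function(joint, node, evidence = NULL) {
  keep <- rep(TRUE, nrow(joint$grid))
  for (nm in names(evidence))
    keep <- keep & joint$grid[[nm]] == evidence[[nm]]
  z <- sum(joint$p[keep])
  vapply(joint$states[[node]], function(s)
    sum(joint$p[keep & joint$grid[[node]] == s]) / z, numeric(1))
}

# mutual information (bits) of two nodes from the enumerated joint
oracle_mi <- function(joint, a, b) {
  sa <- joint$states[[a]]; sb <- joint$states[[b]]
  pab <- outer(sa, sb, Vectorize(function(x, y)
    sum(joint$p[joint$grid[[a]] == x & joint$grid[[b]] == y])))
  pab <- pab / sum(joint$p)
  pa <- rowSums(pab); pb <- colSums(pab)
  tot <- 0
  for (i in seq_along(sa)) for (j in seq_along(sb))
    if (pab[i, j] > 0)
      tot <- tot + pab[i, j] * log2(pab[i, j] / (pa[i] * pb[j]))
  tot
}

# finite-difference sensitivity oracle: perturb one CPT entry with
# proportional covariation and recompute the posterior by enumeration
oracle_fd_derivative <- function(net, node, combo_idx, state_idx, target,
                                 target_state, evidence = NULL, h = 1e-5) {
  eval_at <- function(theta) {
    ct <- net$cpts[[node]]
    ncs <- dim(ct$prob)[1]
    cols <- matrix(ct$prob, nrow = ncs)
    col <- cols[, combo_idx]
    rest <- col[-state_idx]
    newcol <- numeric(ncs)
    newcol[state_idx] <- theta
    if (sum(rest) > 1e-12) {
      newcol[-state_idx] <- rest * (1 - theta) / sum(rest)
    } else {
      newcol[-state_idx] <- (1 - theta) / (ncs - 1)
    }
    cols[, combo_idx] <- newcol
    net$cpts[[node]]$prob <- array(cols, dim = dim(ct$prob))
    oracle_posterior(oracle_joint(net), target, evidence)[[target_state]]
  }
  theta0 <- matrix(net$cpts[[node]]$prob, nrow = dim(net$cpts[[node]]$prob)[1])[state_idx, combo_idx]
  (eval_at(theta0 + h) - eval_at(theta0 - h)) / (2 * h)
}

# tiny helper: a two-node chain net used in several tests
two_node_net <- function(p_a1 = 0.3, p_b1_a1 = 0.8, p_b1_a2 = 0.2) {
  bbn(
    nodes = list(A = c("a1", "a2"), B = c("b1", "b2")),
    arcs = list(c("A", "B")),
    cpts = list(
      A = list(parents = character(0), prob = c(p_a1, 1 - p_a1)),
      B = list(parents = "A",
               prob = matrix(c(p_b1_a1, 1 - p_b1_a1, p_b1_a2, 1 - p_b1_a2), 2))
    )
  )
}
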