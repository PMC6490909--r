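#' Construct a discrete Bayesian belief network
#'
#' A `bbn` bundles a directed acyclic graph over discrete nodes with one
#' conditional probability table (CPT) per node. Nodes are declared with an
#' ordered state list; the declared order is meaningful (it breaks ties in
#' [map_state()] and defines ordinal ranks for ordered nodes).
#'
#' @param nodes named list; one entry per node, each either a character
#'   vector of state labels or a list with elements `states` (character,
#'   length >= 2) and optionally `ordinal` (integer vector parallel to
#'   `states` giving a strict total order for ordered nodes).
#' @param arcs two-column character matrix (or list of length-2 vectors)
#'   of directed arcs `parent -> child`.
#' @param cpts named list, one entry per node: a list with elements
#'   `parents` (character, possibly empty; must equal the node's in-arcs)
#'   and `prob`, a numeric array of conditional probabilities with
#'   dimensions `c(n_child_states, n_states_parent1, ...)` — the child
#'   dimension first, parents following in the declared parent order. Each
#'   column (fixed parent combination) must sum to 1.
#' @return an object of class `bbn`.
#' @seealso [validate_bbn()], [infer_posterior()], [write_bbn()]
#' @examples
#' net <- bbn(
#'   nodes = list(A = c("a1", "a2"), B = c("b1", "b2")),
#'   arcs = list(c("A", "B")),
#'   cpts = list(
#'     A = list(parents = character(0), prob = c(0.3, 0.7)),
#'     B = list(parents = "A", prob = matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#'   )
#' )
#' infer_posterior(net, "A", evidence = c(B = "b1"))
#' @export
bbn <- function(nodes, arcs = list(), cpts) {
  stopifnot(is.list(nodes), !is.null(names(nodes)))
  nodes <- lapply(nodes, function(nd) {
    if (is.character(nd)) nd <- list(states = nd)
    if (is.null(nd$ordinal)) nd["ordinal"] <- list(NULL)
    nd[c("states", "ordinal")]
  })
  if (is.list(arcs) && !is.matrix(arcs)) {
    arcs <- if (length(arcs) == 0L) {
      matrix(character(0L), ncol = 2L)
    } else {
      do.call(rbind, lapply(arcs, function(a) matrix(as.character(a), ncol = 2L)))
    }
  }
  colnames(arcs) <- c("parent", "child")
  cpts <- cpts[names(nodes)]
  cpts <- lapply(names(nodes), function(nm) {
    ct <- cpts[[nm]]
    if (is.null(ct)) stop(sprintf("missing CPT for node '%s'", nm), call. = FALSE)
    parents <- as.character(ct$parents %||% character(0L))
    card <- unname(c(length(nodes[[nm]]$states),
                     vapply(parents, function(p) length(nodes[[p]]$states),
                            integer(1L))))
    prob <- array(as.numeric(ct$prob), dim = card)
    list(child = nm, parents = parents, prob = prob)
  })
  names(cpts) <- names(nodes)
  structure(list(nodes = nodes, arcs = arcs, cpts = cpts), class = "bbn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bbn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian belief network: %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  for (nm in names(x$nodes))
    cat(sprintf("  %s [%s]\n", nm, paste(x$nodes[[nm]]$states, collapse = ", ")))
  invisible(x)
}

node_names <- function(net) names(net$nodes)

node_states <- function(net, node) {
  nd <- net$nodes[[node]]
  if (is.null(nd)) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  nd$states
}

parents_of <- function(net, node)
  unname(net$arcs[net$arcs[, "child"] == node, "parent"])

# Kahn topological sort; returns NULL if the arc graph has a cycle
topological_order <- function(net) {
  nms <- node_names(net)
  indeg <- stats::setNames(integer(length(nms)), nms)
  for (ch in net$arcs[, "child"]) indeg[ch] <- indeg[ch] + 1L
  order <- character(0L)
  queue <- nms[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    kids <- net$arcs[net$arcs[, "parent"] == v, "child"]
    for (ch in kids) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(nms)) NULL else order
}

#' Validate a Bayesian belief network
#'
#' Checks all structural and numerical invariants: unique state labels,
#' acyclicity, agreement between arcs and CPT parent sets, CPT dimensions,
#' probabilities in \[0, 1\] and column normalization (tolerance 1e-9).
#' Violations are reported, not raised.
#'
#' @param net a [bbn] object.
#' @return a list with elements `ok` (logical) and `violations`
#'   (character vector naming each offending node or CPT column).
#' @export
validate_bbn <- function(net) {
  v <- character(0L)
  nms <- node_names(net)
  if (anyDuplicated(nms)) v <- c(v, "duplicate node names")
  for (nm in nms) {
    nd <- net$nodes[[nm]]
    if (length(nd$states) < 2L)
      v <- c(v, sprintf("node '%s': fewer than 2 states", nm))
    if (anyDuplicated(nd$states))
      v <- c(v, sprintf("node '%s': duplicate state labels", nm))
    if (!is.null(nd$ordinal)) {
      if (length(nd$ordinal) != length(nd$states) || anyDuplicated(nd$ordinal))
        v <- c(v, sprintf("node '%s': ordinal ranks are not a strict total order", nm))
    }
  }
  bad_arc <- !(net$arcs[, "parent"] %in% nms) | !(net$arcs[, "child"] %in% nms)
  if (any(bad_arc)) v <- c(v, "arc references unknown node")
  if (any(bad_arc)) return(list(ok = FALSE, violations = v))
  if (is.null(topological_order(net))) v <- c(v, "cycle in arc graph")
  for (nm in nms) {
    ct <- net$cpts[[nm]]
    inarcs <- sort(parents_of(net, nm))
    if (!identical(sort(ct$parents), inarcs)) {
      v <- c(v, sprintf("node '%s': CPT parents do not match in-arcs", nm))
      next
    }
    card <- unname(c(length(node_states(net, nm)),
                     vapply(ct$parents, function(p) length(node_states(net, p)),
                            integer(1L))))
    if (!identical(as.integer(dim(ct$prob)), as.integer(card))) {
      v <- c(v, sprintf("node '%s': CPT dimensions do not match state counts", nm))
      next
    }
    p <- ct$prob
    if (any(p < 0 | p > 1))
      v <- c(v, sprintf("node '%s': CPT entries outside [0, 1]", nm))
    cols <- matrix(p, nrow = card[1L])
    csum <- colSums(cols)
    bad <- which(abs(csum - 1) > 1e-9)
    for (j in bad)
      v <- c(v, sprintf("node '%s': CPT column %d not normalized (sum %.6g)", nm, j, csum[j]))
  }
  list(ok = length(v) == 0L, violations = v)
}

.check_assignment <- function(net, assignment, nodes = node_names(net)) {
  assignment <- unlist(assignment)
  missing <- setdiff(nodes, names(assignment))
  if (length(missing))
    stop("assignment missing node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (nm in intersect(names(assignment), node_names(net))) {
    if (!(assignment[[nm]] %in% node_states(net, nm)))
      stop(sprintf("'%s' is not a state of node '%s'", assignment[[nm]], nm), call. = FALSE)
  }
  unknown <- setdiff(names(assignment), node_names(net))
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  assignment
}

#' Joint probability of a full assignment
#'
#' Evaluates the factored joint: the product over nodes of the CPT entry
#' selected by the assignment.
#'
#' @param net a [bbn] object.
#' @param assignment named character vector or list mapping every node to
#'   one of its states.
#' @return a single probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- .check_assignment(net, assignment)
  p <- 1
  for (nm in node_names(net)) {
    ct <- net$cpts[[nm]]
    idx <- c(match(assignment[[nm]], node_states(net, nm)),
             vapply(ct$parents,
                    function(pa) match(assignment[[pa]], node_states(net, pa)),
                    integer(1L)))
    p <- p * do.call(`[`, c(list(ct$prob), as.list(idx)))
  }
  p
}

cpt_factor <- function(net, node) {
  ct <- net$cpts[[node]]
  vars <- c(node, ct$parents)
  new_factor(vars, lapply(vars, function(v) node_states(net, v)), ct$prob)
}

.check_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) return(character(0L))
  evidence <- unlist(evidence)
  for (nm in names(evidence)) {
    if (!(nm %in% node_names(net)))
      stop(sprintf("evidence on unknown node '%s'", nm), call. = FALSE)
    if (!(evidence[[nm]] %in% node_states(net, nm)))
      stop(sprintf("'%s' is not a state of node '%s'", evidence[[nm]], nm), call. = FALSE)
  }
  evidence
}

# dynamic min-fill elimination order over the factor interaction graph
min_fill_order <- function(scopes, elim) {
  adj <- stats::setNames(lapply(elim, function(v) character(0L)), elim)
  for (sc in scopes) {
    sc <- intersect(sc, elim)
    for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  }
  order <- character(0L)
  remaining <- elim
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], remaining)
      if (length(nb) < 2L) return(0L)
      m <- 0L
      for (i in seq_len(length(nb) - 1L))
        for (j in seq(i + 1L, length(nb)))
          if (!(nb[j] %in% adj[[nb[i]]])) m <- m + 1L
      m
    }, integer(1L))
    v <- remaining[which.min(fill)]  # ties: first in declared order
    nb <- intersect(adj[[v]], remaining)
    for (a in nb) adj[[a]] <- union(adj[[a]], setdiff(nb, a))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

# Variable elimination. Returns the unnormalized factor over `keep`
# (permuted into `keep` order) with attribute "log_const" holding the log of
# the constant extracted by per-step renormalization, so that
# sum(values) * exp(log_const) = P(evidence).
run_ve <- function(net, keep, evidence, elim_order = NULL) {
  evidence <- .check_evidence(net, evidence)
  factors <- lapply(node_names(net), function(nm) cpt_factor(net, nm))
  for (nm in names(evidence))
    factors <- lapply(factors, function(f)
      if (nm %in% f$vars) factor_reduce(f, nm, evidence[[nm]]) else f)
  scalar <- 0  # log of scalar constants absorbed so far
  is_scalar <- vapply(factors, function(f) length(f$vars) == 0L, logical(1L))
  for (f in factors[is_scalar]) {
    if (f$values == 0) return(.zero_ve(net, keep))
    scalar <- scalar + log(f$values)
  }
  factors <- factors[!is_scalar]
  elim <- setdiff(node_names(net), union(keep, names(evidence)))
  if (is.null(elim_order)) {
    elim_order <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
  } else {
    stopifnot(setequal(elim_order, elim))
  }
  for (v in elim_order) {
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1L))
    if (!any(inv)) next
    prod_f <- Reduce(factor_product, factors[inv])
    prod_f <- factor_marginalize(prod_f, v)
    tot <- sum(prod_f$values)
    if (tot == 0) return(.zero_ve(net, keep))
    # renormalize per elimination step to bound underflow
    prod_f$values <- prod_f$values / tot
    scalar <- scalar + log(tot)
    factors <- c(factors[!inv], if (length(prod_f$vars)) list(prod_f))
  }
  out <- Reduce(factor_product, factors,
                new_factor(character(0L), list(), 1))
  # evidence nodes requested in keep enter as point masses
  for (nm in intersect(keep, names(evidence))) {
    st <- node_states(net, nm)
    pm <- new_factor(nm, list(st), as.numeric(st == evidence[[nm]]))
    out <- factor_product(out, pm)
  }
  out <- factor_permute(out, keep)
  attr(out, "log_const") <- scalar
  out
}

.zero_ve <- function(net, keep) {
  out <- new_factor(keep, lapply(keep, function(v) node_states(net, v)),
                    numeric(prod(vapply(keep, function(v) length(node_states(net, v)),
                                        integer(1L)))))
  attr(out, "log_const") <- 0
  out
}

#' Probability of evidence
#'
#' @param net a [bbn] object.
#' @param evidence named character vector mapping observed nodes to states.
#' @return the marginal probability of the evidence configuration.
#' @export
evidence_probability <- function(net, evidence = NULL) {
  f <- run_ve(net, character(0L), evidence)
  sum(f$values) * exp(attr(f, "log_const"))
}

#' Exact posterior distributions by variable elimination
#'
#' Computes, for each target node, the exact conditional distribution given
#' the evidence. With empty evidence the prior marginals are returned. The
#' result is independent of the elimination order; by default a min-fill
#' heuristic order is used.
#'
#' @param net a [bbn] object.
#' @param targets character vector of query nodes.
#' @param evidence named character vector (or empty/`NULL`) of observed states.
#' @param elim_order optional explicit elimination order (a permutation of
#'   the non-target, non-evidence nodes); results do not depend on it.
#' @return a named list (one element per target) of `bbn_posterior`
#'   objects: named probability vectors with attributes `node` and
#'   `evidence`.
#' @export
infer_posterior <- function(net, targets, evidence = NULL, elim_order = NULL) {
  evidence <- .check_evidence(net, evidence)
  out <- lapply(targets, function(tg) {
    if (!(tg %in% node_names(net)))
      stop(sprintf("unknown node '%s'", tg), call. = FALSE)
    f <- run_ve(net, tg, evidence, elim_order = elim_order)
    tot <- sum(f$values)
    if (tot == 0)
      stop("impossible evidence: the evidence configuration has probability 0",
           call. = FALSE)
    p <- stats::setNames(f$values / tot, node_states(net, tg))
    structure(p, node = tg, evidence = evidence, class = "bbn_posterior")
  })
  names(out) <- targets
  out
}

#' @export
print.bbn_posterior <- function(x, ...) {
  ev <- attr(x, "evidence")
  evtxt <- if (length(ev)) paste(names(ev), unlist(ev), sep = "=", collapse = ", ")
           else "(none)"
  cat(sprintf("Posterior of %s | evidence: %s\n", attr(x, "node"), evtxt))
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Maximum a-posteriori state of a node
#'
#' Returns the argmax state of the posterior given the evidence; ties are
#' broken deterministically by the declared state order (first state wins).
#' If the node itself is in the evidence, its evidenced state is returned
#' (after checking that the evidence has positive probability).
#'
#' @inheritParams infer_posterior
#' @param node the query node.
#' @return a single state label.
#' @export
map_state <- function(net, node, evidence = NULL) {
  evidence <- .check_evidence(net, evidence)
  if (node %in% names(evidence)) {
    if (evidence_probability(net, evidence) == 0)
      stop("impossible evidence: the evidence configuration has probability 0",
           call. = FALSE)
    return(evidence[[node]])
  }
  post <- infer_posterior(net, node, evidence)[[1L]]
  names(post)[which.max(post)]  # which.max returns the first maximum
}
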