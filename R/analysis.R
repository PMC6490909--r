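# Model interrogation: mutual-information arc strengths, posterior
# sensitivity analysis under proportional covariation, k-fold
# cross-validation, and evidence-scenario comparison.

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Arc strength as mutual information
#'
#' The strength of an arc is the mutual information I(parent; child), in
#' bits, of the two endpoints under the network's joint distribution. It
#' is symmetric, non-negative, and zero exactly when the endpoints are
#' independent.
#'
#' @param net a [bbn] object.
#' @param parent,child endpoints of an existing arc.
#' @return mutual information in bits.
#' @export
arc_strength <- function(net, parent, child) {
  has <- any(net$arcs[, "parent"] == parent & net$arcs[, "child"] == child)
  if (!has)
    stop(sprintf("no arc %s -> %s in the network", parent, child), call. = FALSE)
  f <- run_ve(net, c(parent, child), NULL)
  p <- matrix(f$values / sum(f$values),
              nrow = length(node_states(net, parent)))
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

#' Arc strengths for every arc
#'
#' @param net a [bbn] object.
#' @return data frame with columns `parent`, `child`, `strength_bits`.
#' @export
arc_strengths <- function(net) {
  data.frame(
    parent = net$arcs[, "parent"],
    child = net$arcs[, "child"],
    strength_bits = vapply(seq_len(nrow(net$arcs)), function(i)
      arc_strength(net, net$arcs[i, "parent"], net$arcs[i, "child"]),
      numeric(1L)),
    stringsAsFactors = FALSE
  )
}

# ---- d-separation --------------------------------------------------------

# Moral-ancestral-graph d-separation test: X independent of Y given Z?
# arcs: 2-col matrix. X, Y, Z: character vectors.
dsep <- function(arcs, nodes, x, y, z) {
  # ancestors of x, y, z (including themselves)
  anc <- unique(c(x, y, z))
  repeat {
    pa <- arcs[arcs[, "child"] %in% anc, "parent"]
    new <- setdiff(pa, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sub <- arcs[arcs[, "parent"] %in% anc & arcs[, "child"] %in% anc, , drop = FALSE]
  # moralize: undirected edges = arcs + marriages between co-parents
  edges <- rbind(sub, sub[, c("child", "parent"), drop = FALSE])
  for (ch in unique(sub[, "child"])) {
    pa <- sub[sub[, "child"] == ch, "parent"]
    if (length(pa) > 1L) {
      pairs <- utils::combn(pa, 2L)
      edges <- rbind(edges, t(pairs), t(pairs[2:1, , drop = FALSE]))
    }
  }
  colnames(edges) <- c("parent", "child")
  # remove evidence nodes, test reachability x -> y
  keep <- setdiff(anc, z)
  edges <- edges[edges[, 1L] %in% keep & edges[, 2L] %in% keep, , drop = FALSE]
  reach <- intersect(x, keep)
  repeat {
    nb <- edges[edges[, 1L] %in% reach, 2L]
    new <- setdiff(nb, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  !any(y %in% reach)
}

# Is the CPT of `node` irrelevant to P(target | evidence)? Modelled by an
# auxiliary parameter parent of `node` and a d-separation test.
.param_irrelevant <- function(net, node, target, evidence_nodes) {
  aux <- ".theta."
  arcs <- rbind(net$arcs, c(aux, node))
  dsep(arcs, c(node_names(net), aux), aux, target, evidence_nodes)
}

# posterior of target with one CPT column perturbed: entry `state_idx` of
# the column for parent combo `combo_idx` set to theta, remaining entries
# covaried proportionally
.posterior_with_theta <- function(net, node, combo_idx, state_idx, theta,
                                  target, evidence) {
  ct <- net$cpts[[node]]
  ncs <- dim(ct$prob)[1L]
  cols <- matrix(ct$prob, nrow = ncs)
  col <- cols[, combo_idx]
  theta0 <- col[state_idx]
  rest <- col[-state_idx]
  newcol <- numeric(ncs)
  newcol[state_idx] <- theta
  if (sum(rest) > 1e-12) {
    newcol[-state_idx] <- rest * (1 - theta) / sum(rest)
  } else {
    newcol[-state_idx] <- (1 - theta) / (ncs - 1L)
  }
  cols[, combo_idx] <- newcol
  net$cpts[[node]]$prob <- array(cols, dim = dim(ct$prob))
  as.numeric(infer_posterior(net, target, evidence)[[1L]])
}

#' Posterior sensitivity analysis
#'
#' For every conditional-probability parameter of the selected nodes,
#' computes the derivative of each target-state posterior with respect to
#' that parameter under proportional covariation (the remaining entries of
#' the perturbed column are rescaled to keep it normalized). Derivatives
#' are evaluated by central finite differences with step `h`; parameters
#' of nodes d-separated from the target given the evidence are exactly 0
#' without numerical evaluation.
#'
#' @param net a [bbn] object.
#' @param target the target node (must not be in the evidence).
#' @param evidence named character vector of observed states (optional).
#' @param nodes nodes whose CPT parameters are analysed (default: all).
#' @param h finite-difference step.
#' @return an object of class `sensitivity_report`: a list with
#'   `parameters` (one row per parameter x target state: node,
#'   parent combination, state, target state, value of the parameter,
#'   derivative) and `node_aggregate` (per node, the maximum absolute
#'   derivative, sorted descending with a rank column).
#' @export
sensitivity_analysis <- function(net, target, evidence = NULL,
                                 nodes = node_names(net), h = 1e-4) {
  evidence <- .check_evidence(net, evidence)
  if (target %in% names(evidence))
    stop("target node is part of the evidence", call. = FALSE)
  if (!(target %in% node_names(net)))
    stop(sprintf("unknown node '%s'", target), call. = FALSE)
  tstates <- node_states(net, target)
  rows <- list()
  for (nm in nodes) {
    ct <- net$cpts[[nm]]
    ncs <- dim(ct$prob)[1L]
    cols <- matrix(ct$prob, nrow = ncs)
    keys <- .combo_keys(net, ct$parents)
    irrelevant <- .param_irrelevant(net, nm, target, names(evidence))
    for (j in seq_along(keys)) for (s in seq_len(ncs)) {
      theta0 <- cols[s, j]
      if (irrelevant) {
        d <- numeric(length(tstates))
      } else {
        up <- min(theta0 + h, 1)
        dn <- max(theta0 - h, 0)
        p_up <- .posterior_with_theta(net, nm, j, s, up, target, evidence)
        p_dn <- .posterior_with_theta(net, nm, j, s, dn, target, evidence)
        d <- (p_up - p_dn) / (up - dn)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        node = nm, parent_combo = keys[j], state = node_states(net, nm)[s],
        target_state = tstates, theta = theta0, derivative = d,
        stringsAsFactors = FALSE
      )
    }
  }
  params <- do.call(rbind, rows)
  agg <- stats::aggregate(abs(params$derivative),
                          by = list(node = params$node), FUN = max)
  names(agg)[2L] <- "max_abs_derivative"
  agg <- agg[order(-agg$max_abs_derivative, match(agg$node, node_names(net))), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  structure(list(target = target, evidence = evidence,
                 parameters = params, node_aggregate = agg),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity of '%s' (%d parameters analysed)\n",
              x$target, nrow(x$parameters) / length(unique(x$parameters$target_state))))
  print(x$node_aggregate)
  invisible(x)
}

# ---- cross-validation ----------------------------------------------------

#' K-fold cross-validation of node prediction
#'
#' Shuffles the records with the given seed, splits them into `k`
#' near-equal folds (sizes differ by at most one), and for each fold
#' relearns the CPTs of `nodes_to_learn` on the remaining folds, then
#' predicts the held-out node for every test row by its MAP state given
#' all other observed columns as evidence. Reports per-fold prediction
#' accuracy and mean log-loss, and their averages.
#'
#' @param net a [bbn] object (expert CPTs, if any, stay fixed).
#' @param records data frame of discretized state assignments.
#' @param k number of folds, `2 <= k <= nrow(records)`.
#' @param node the node to predict.
#' @param nodes_to_learn nodes relearned on each training split (default:
#'   every node with a column in `records`).
#' @param alpha pseudocount used when learning (see [learn_cpts()]).
#' @param seed integer seed for the fold shuffle.
#' @return an object of class `cv_result`: list with `folds` (data frame
#'   fold / n_test / accuracy / logloss), `mean_accuracy`, `mean_logloss`,
#'   `k`, `node`, `seed`.
#' @export
kfold_cv <- function(net, records, k, node, nodes_to_learn = NULL, alpha = 1,
                     seed = 1L) {
  n <- nrow(records)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of records", call. = FALSE)
  if (is.null(nodes_to_learn))
    nodes_to_learn <- intersect(node_names(net), names(records))
  ev_cols <- setdiff(intersect(node_names(net), names(records)), node)
  idx <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)[order(idx)]
  res <- lapply(seq_len(k), function(f) {
    train <- records[fold_of != f, , drop = FALSE]
    test <- records[fold_of == f, , drop = FALSE]
    net_f <- learn_cpts(net, train, nodes = nodes_to_learn, alpha = alpha)
    # deduplicate evidence patterns: one inference per unique pattern
    pat <- do.call(paste, c(test[ev_cols], sep = "\r"))
    upat <- !duplicated(pat)
    preds <- character(sum(upat))
    posts <- vector("list", sum(upat))
    urows <- which(upat)
    for (i in seq_along(urows)) {
      ev <- unlist(test[urows[i], ev_cols, drop = FALSE])
      post <- infer_posterior(net_f, node, ev)[[1L]]
      posts[[i]] <- post
      preds[i] <- names(post)[which.max(post)]
    }
    map_idx <- match(pat, pat[upat])
    pred <- preds[map_idx]
    truth <- test[[node]]
    pt <- vapply(seq_len(nrow(test)), function(r)
      as.numeric(posts[[map_idx[r]]][truth[r]]), numeric(1L))
    data.frame(fold = f, n_test = nrow(test),
               accuracy = mean(pred == truth),
               logloss = mean(-log(pt)))
  })
  folds <- do.call(rbind, res)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 mean_logloss = mean(folds$logloss),
                 k = k, node = node, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation for node '%s'\n", x$k, x$node))
  print(x$folds, row.names = FALSE)
  cat(sprintf("mean accuracy %.4f, mean log-loss %.4f\n",
              x$mean_accuracy, x$mean_logloss))
  invisible(x)
}

# ---- scenarios -----------------------------------------------------------

#' Compare posterior distributions across evidence scenarios
#'
#' Computes the posterior of every queried node under each scenario's
#' evidence, always prepending the empty-evidence baseline, together with
#' the mutual-information strength of every arc.
#'
#' @param net a [bbn] object.
#' @param scenarios named list of evidence vectors (possibly empty); names
#'   label the scenarios.
#' @param query character vector of nodes to query.
#' @return an object of class `scenario_table`: list with `posteriors`
#'   (data frame scenario / node / state / probability) and
#'   `arc_strengths` (see [arc_strengths()]).
#' @export
scenario_compare <- function(net, scenarios, query) {
  sc <- c(list(baseline = character(0L)), scenarios)
  rows <- list()
  for (lab in names(sc)) {
    posts <- infer_posterior(net, query, sc[[lab]])
    for (nd in query) {
      p <- posts[[nd]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = lab, node = nd, state = names(p),
        probability = as.numeric(p), stringsAsFactors = FALSE)
    }
  }
  structure(list(posteriors = do.call(rbind, rows),
                 arc_strengths = arc_strengths(net)),
            class = "scenario_table")
}
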