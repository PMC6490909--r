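# Maximum-likelihood CPT estimation with optional Laplace-style
# pseudocounts, and the log-likelihood diagnostic used by cross-validation.

#' Learn CPTs by maximum likelihood
#'
#' For each node to learn, estimates
#' \eqn{P(child = s | parents = p) = (count(s, p) + \alpha) /
#' (count(p) + \alpha |states|)}. With `alpha = 0` the estimate is the raw
#' relative frequency and an unobserved parent combination is an error;
#' with `alpha > 0` unseen combinations fall back to the uniform
#' distribution. CPTs of nodes not in `nodes` (e.g. the expert nodes) are
#' left untouched.
#'
#' @param net a [bbn] object supplying structure and state catalogues.
#' @param records data frame of discretized state assignments; must
#'   contain a column for every node to learn and for all its parents.
#' @param nodes character vector of nodes whose CPTs are estimated
#'   (default: every node with a column in `records`).
#' @param alpha pseudocount per child-state cell, >= 0 and finite.
#' @param missing how to handle `NA`s: `"complete-case"` drops, per node,
#'   the rows with `NA` in the node or its parents; `"error"` aborts.
#' @return `net` with the selected CPTs replaced by their estimates.
#' @export
learn_cpts <- function(net, records, nodes = NULL, alpha = 1,
                       missing = c("complete-case", "error")) {
  missing <- match.arg(missing)
  stopifnot(is.finite(alpha), alpha >= 0)
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  if (is.null(nodes)) nodes <- intersect(node_names(net), names(records))
  for (nm in nodes) {
    ct <- net$cpts[[nm]]
    need <- c(nm, ct$parents)
    miss_col <- setdiff(need, names(records))
    if (length(miss_col))
      stop(sprintf("records lack column(s) %s needed to learn '%s'",
                   paste(miss_col, collapse = ", "), nm), call. = FALSE)
    sub <- records[need]
    has_na <- Reduce(`|`, lapply(sub, is.na))
    if (any(has_na)) {
      if (missing == "error") stop("missing values in records", call. = FALSE)
      sub <- sub[!has_na, , drop = FALSE]
    }
    for (v in need) {
      bad <- !(sub[[v]] %in% node_states(net, v))
      if (any(bad))
        stop(sprintf("illegal state(s) for '%s': %s", v,
                     paste(unique(sub[[v]][bad]), collapse = ", ")), call. = FALSE)
    }
    fl <- lapply(need, function(v) factor(sub[[v]], levels = node_states(net, v)))
    counts <- table(fl)  # array: child x parents, matching CPT layout
    card <- dim(counts)
    ncs <- card[1L]
    cols <- matrix(as.numeric(counts), nrow = ncs)
    csum <- colSums(cols)
    if (alpha == 0 && any(csum == 0))
      stop(sprintf("node '%s': unobserved parent combination with alpha = 0", nm),
           call. = FALSE)
    est <- sweep(cols + alpha, 2L, csum + alpha * ncs, `/`)
    net$cpts[[nm]]$prob <- array(est, dim = dim(ct$prob))
  }
  net
}

#' Total log-likelihood of records under a network
#'
#' Sums, over the rows of `records`, the log-probability of the observed
#' assignment. Fully observed rows are evaluated directly on the factored
#' joint; rows observing only a subset of nodes (`NA` elsewhere) are
#' evaluated as marginal evidence probabilities via exact inference.
#'
#' @inheritParams learn_cpts
#' @return total log-likelihood (can be `-Inf` if a record has
#'   probability 0).
#' @export
loglikelihood <- function(net, records) {
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  nms <- intersect(node_names(net), names(records))
  full <- setequal(nms, node_names(net))
  ll <- 0
  if (full) {
    ok_rows <- !Reduce(`|`, lapply(records[nms], is.na))
  } else {
    ok_rows <- rep(FALSE, nrow(records))
  }
  # fast path: fully observed rows scored as sums of log CPT entries
  if (any(ok_rows)) {
    sub <- records[ok_rows, nms, drop = FALSE]
    lp <- numeric(nrow(sub))
    for (nm in node_names(net)) {
      ct <- net$cpts[[nm]]
      card <- dim(ct$prob)
      assn <- cbind(match(sub[[nm]], node_states(net, nm)))
      for (pa in ct$parents)
        assn <- cbind(assn, match(sub[[pa]], node_states(net, pa)))
      if (anyNA(assn)) stop("records contain illegal states", call. = FALSE)
      lp <- lp + log(ct$prob[.lindex(assn, card)])
    }
    ll <- ll + sum(lp)
  }
  # general path: partially observed rows via evidence probability
  for (i in which(!ok_rows)) {
    obs <- records[i, nms, drop = FALSE]
    ev <- unlist(obs[!is.na(unlist(obs))])
    if (length(ev) == 0L) next
    ll <- ll + log(evidence_probability(net, ev))
  }
  ll
}
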