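# JSON (de)serialization of bbn objects.
#
# Schema: {nodes:[{name, states, ordinal?}], arcs:[[parent, child], ...],
#          cpts:{child:{parents:[...], table:{"p1state|p2state|...": [probs]}}}}
# The combo key joins parent states with "|" in declared parent order; a
# root node has the single key "(root)". Round-trips are loss-free.

.combo_keys <- function(net, parents) {
  if (length(parents) == 0L) return("(root)")
  card <- vapply(parents, function(p) length(node_states(net, p)), integer(1L))
  assn <- arrayInd(seq_len(prod(card)), card)
  apply(assn, 1L, function(row)
    paste(mapply(function(p, i) node_states(net, p)[i], parents, row),
          collapse = "|"))
}

bbn_to_list <- function(net) {
  nodes <- lapply(node_names(net), function(nm) {
    nd <- net$nodes[[nm]]
    out <- list(name = nm, states = as.list(nd$states))
    if (!is.null(nd$ordinal)) out$ordinal <- as.list(as.integer(nd$ordinal))
    out
  })
  arcs <- lapply(seq_len(nrow(net$arcs)), function(i) as.list(net$arcs[i, ]))
  cpts <- lapply(node_names(net), function(nm) {
    ct <- net$cpts[[nm]]
    ncs <- length(node_states(net, nm))
    cols <- matrix(ct$prob, nrow = ncs)
    keys <- .combo_keys(net, ct$parents)
    tab <- lapply(seq_along(keys), function(j) as.numeric(cols[, j]))
    names(tab) <- keys
    list(parents = as.list(ct$parents), table = tab)
  })
  names(cpts) <- node_names(net)
  list(nodes = nodes, arcs = arcs, cpts = cpts)
}

list_to_bbn <- function(x) {
  nodes <- stats::setNames(lapply(x$nodes, function(nd) {
    out <- list(states = unlist(nd$states))
    if (!is.null(nd$ordinal)) out$ordinal <- as.integer(unlist(nd$ordinal))
    out
  }), vapply(x$nodes, function(nd) nd$name, character(1L)))
  arcs <- lapply(x$arcs, function(a) unlist(a))
  cpts <- lapply(names(nodes), function(nm) {
    ct <- x$cpts[[nm]]
    parents <- as.character(unlist(ct$parents))
    ncs <- length(nodes[[nm]]$states)
    card <- vapply(parents, function(p) length(nodes[[p]]$states), integer(1L))
    ncol <- if (length(card)) prod(card) else 1L
    cols <- matrix(NA_real_, nrow = ncs, ncol = ncol)
    if (length(parents) == 0L) {
      # a root CPT has exactly one column; accept any single key
      if (length(ct$table) != 1L)
        stop(sprintf("CPT for '%s': expected a single root column", nm),
             call. = FALSE)
      cols[, 1L] <- unlist(ct$table[[1L]])
      return(list(parents = parents, prob = array(cols, dim = ncs)))
    }
    keys <- {
      assn <- arrayInd(seq_len(ncol), card)
      apply(assn, 1L, function(row)
        paste(mapply(function(p, i) nodes[[p]]$states[i], parents, row),
              collapse = "|"))
    }
    for (j in seq_along(keys)) {
      col <- ct$table[[keys[j]]]
      if (is.null(col))
        stop(sprintf("CPT for '%s': missing parent combination '%s'", nm, keys[j]),
             call. = FALSE)
      cols[, j] <- unlist(col)
    }
    list(parents = parents, prob = array(cols, dim = c(ncs, card)))
  })
  names(cpts) <- names(nodes)
  bbn(nodes = nodes, arcs = arcs, cpts = cpts)
}

#' Write a network to JSON
#'
#' @param net a [bbn] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bbn <- function(net, path) {
  # digits = I(17): bit-exact round trip of the probabilities
  jsonlite::write_json(bbn_to_list(net), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by [write_bbn()] (or hand-authored in the same
#'   schema).
#' @return a [bbn] object.
#' @export
read_bbn <- function(path) {
  list_to_bbn(jsonlite::read_json(path))
}
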