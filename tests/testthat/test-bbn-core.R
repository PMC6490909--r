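# Core network representation, validation and exact inference.

test_that("validation passes sound networks and names violations", {
  expect_true(validate_bbn(two_node_net())$ok)

  cyc <- bbn(
    nodes = list(A = c("a1", "a2"), B = c("b1", "b2")),
    arcs = list(c("A", "B"), c("B", "A")),
    cpts = list(
      A = list(parents = "B", prob = matrix(0.5, 2, 2)),
      B = list(parents = "A", prob = matrix(0.5, 2, 2))
    )
  )
  chk <- validate_bbn(cyc)
  expect_false(chk$ok)
  expect_true(any(grepl("cycle", chk$violations)))

  bad <- two_node_net()
  bad$cpts$A$prob <- array(c(0.6, 0.6), dim = 2L)
  chk <- validate_bbn(bad)
  expect_false(chk$ok)
  expect_true(any(grepl("not normalized", chk$violations)))
  expect_true(any(grepl("'A'", chk$violations)))
})

test_that("joint probability is the product of selected CPT entries", {
  chain <- bbn(
    nodes = list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2")),
    arcs = list(c("A", "B"), c("B", "C")),
    cpts = list(
      A = list(parents = character(0), prob = c(0.5, 0.5)),
      B = list(parents = "A", prob = matrix(0.5, 2, 2)),
      C = list(parents = "B", prob = matrix(0.5, 2, 2))
    )
  )
  expect_equal(joint_probability(chain, c(A = "a1", B = "b2", C = "c1")), 0.125)

  expect_equal(joint_probability(two_node_net(), c(A = "a1", B = "b1")),
               0.3 * 0.8)

  zero <- two_node_net(p_b1_a1 = 0)
  expect_equal(joint_probability(zero, c(A = "a1", B = "b1")), 0)

  expect_error(joint_probability(two_node_net(), c(A = "a1")), "missing")
  expect_error(joint_probability(two_node_net(), c(A = "a1", B = "nope")),
               "not a state")
})

test_that("posteriors match the Bayes-rule worked example", {
  post <- infer_posterior(two_node_net(), "A", evidence = c(B = "b1"))[[1]]
  expect_equal(as.numeric(post["a1"]), 12 / 19, tolerance = 1e-12)
  expect_equal(as.numeric(post["a2"]), 7 / 19, tolerance = 1e-12)

  # empty evidence on a root returns its prior
  prior <- infer_posterior(two_node_net(), "A")[[1]]
  expect_equal(as.numeric(prior), c(0.3, 0.7))
})

test_that("variable elimination agrees with full-joint enumeration", {
  for (seed in 1:20) {
    net <- random_bbn(seed)
    joint <- oracle_joint(net)
    nms <- names(net$nodes)
    # empty evidence
    for (nd in nms) {
      got <- as.numeric(infer_posterior(net, nd)[[1]])
      expect_equal(got, unname(oracle_posterior(joint, nd)), tolerance = 1e-10)
    }
    # single-node evidence on the last node's first state (when possible)
    ev_node <- nms[length(nms)]
    ev <- stats::setNames(net$nodes[[ev_node]]$states[1], ev_node)
    if (sum(joint$p[joint$grid[[ev_node]] == ev]) > 0) {
      for (nd in setdiff(nms, ev_node)) {
        got <- as.numeric(infer_posterior(net, nd, ev)[[1]])
        expect_equal(got, unname(oracle_posterior(joint, nd, ev)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("posteriors are normalized and elimination-order invariant", {
  net <- random_bbn(101)
  nms <- names(net$nodes)
  ev <- stats::setNames(net$nodes[[nms[2]]]$states[1], nms[2])
  target <- nms[1]
  elim <- setdiff(nms, c(target, names(ev)))
  p1 <- infer_posterior(net, target, ev, elim_order = elim)[[1]]
  p2 <- infer_posterior(net, target, ev, elim_order = rev(elim))[[1]]
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-10)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
})

test_that("conditioning on a node yields a point mass when queried", {
  net <- two_node_net()
  post <- infer_posterior(net, "B", evidence = c(B = "b1"))[[1]]
  expect_equal(as.numeric(post), c(1, 0))
})

test_that("impossible evidence raises an explicit error", {
  net <- two_node_net(p_a1 = 1, p_b1_a1 = 1)  # B=b2 has probability 0
  expect_error(infer_posterior(net, "A", c(B = "b2")), "impossible evidence")
  expect_error(map_state(net, "A", c(B = "b2")), "impossible evidence")
  expect_error(infer_posterior(net, "A", c(B = "zzz")), "not a state")
  expect_error(infer_posterior(net, "A", c(Z = "b1")), "unknown node")
})

test_that("map_state takes the argmax with declared-order tie break", {
  net <- bbn(
    nodes = list(X = c("x1", "x2", "x3")),
    arcs = list(),
    cpts = list(X = list(parents = character(0), prob = c(0.2, 0.5, 0.3)))
  )
  expect_equal(map_state(net, "X"), "x2")

  tie <- bbn(
    nodes = list(X = c("x1", "x2")),
    arcs = list(),
    cpts = list(X = list(parents = character(0), prob = c(0.5, 0.5)))
  )
  expect_equal(map_state(tie, "X"), "x1")

  expect_equal(map_state(two_node_net(), "B", c(B = "b2")), "b2")
})
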