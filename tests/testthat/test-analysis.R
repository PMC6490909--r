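# Arc strength, sensitivity analysis, cross-validation, scenarios.

copy_net <- function(p_copy = 1, p_x1 = 0.5) {
  bbn(
    nodes = list(X = c("x1", "x2"), Y = c("y1", "y2")),
    arcs = list(c("X", "Y")),
    cpts = list(
      X = list(parents = character(0), prob = c(p_x1, 1 - p_x1)),
      Y = list(parents = "X",
               prob = matrix(c(p_copy, 1 - p_copy, 1 - p_copy, p_copy), 2))
    )
  )
}

test_that("arc strength is mutual information in bits", {
  # child independent of parent -> 0
  indep <- copy_net(p_copy = 0.5)
  expect_equal(arc_strength(indep, "X", "Y"), 0, tolerance = 1e-12)
  # deterministic copy of a uniform binary parent -> 1 bit
  expect_equal(arc_strength(copy_net(1), "X", "Y"), 1, tolerance = 1e-12)
  expect_error(arc_strength(copy_net(1), "Y", "X"), "no arc")
  # arbitrary 3-state joints match brute-force MI from the enumerated joint
  for (seed in c(3, 9, 27)) {
    set.seed(seed)
    pa <- rgamma(3, 1); pa <- pa / sum(pa)
    cols <- matrix(rgamma(9, 1), 3); cols <- sweep(cols, 2, colSums(cols), `/`)
    net <- bbn(
      nodes = list(A = paste0("a", 1:3), B = paste0("b", 1:3)),
      arcs = list(c("A", "B")),
      cpts = list(A = list(parents = character(0), prob = pa),
                  B = list(parents = "A", prob = cols))
    )
    expect_equal(arc_strength(net, "A", "B"),
                 oracle_mi(oracle_joint(net), "A", "B"), tolerance = 1e-10)
  }
})

test_that("arc strength is symmetric in its endpoints", {
  net <- random_bbn(33)
  joint <- oracle_joint(net)
  a <- net$arcs[1, "parent"]; b <- net$arcs[1, "child"]
  expect_equal(oracle_mi(joint, a, b), oracle_mi(joint, b, a), tolerance = 1e-12)
  expect_equal(arc_strength(net, a, b), oracle_mi(joint, a, b), tolerance = 1e-10)
})

test_that("the two-node sensitivity derivative matches the closed form", {
  net <- two_node_net()  # P(a1)=0.3, P(b1|a1)=0.8, P(b1|a2)=0.2
  rep <- sensitivity_analysis(net, "A", evidence = c(B = "b1"), nodes = "B")
  row <- rep$parameters[rep$parameters$parent_combo == "a1" &
                        rep$parameters$state == "b1" &
                        rep$parameters$target_state == "a1", ]
  closed <- (0.3 * 0.2 * 0.7) / (0.3 * 0.8 + 0.7 * 0.2)^2
  expect_equal(row$derivative, closed, tolerance = 1e-6)
})

test_that("sensitivity derivatives match an independent finite-difference oracle", {
  net <- random_bbn(7, max_nodes = 5, max_states = 3)
  nms <- names(net$nodes)
  target <- nms[length(nms)]
  rep <- sensitivity_analysis(net, target)
  for (k in seq_len(min(25, nrow(rep$parameters)))) {
    row <- rep$parameters[k, ]
    ct <- net$cpts[[row$node]]
    keys <- nutribbn:::.combo_keys(net, ct$parents)
    j <- match(row$parent_combo, keys)
    s <- match(row$state, net$nodes[[row$node]]$states)
    want <- oracle_fd_derivative(net, row$node, j, s, target,
                                 row$target_state, h = 1e-5)
    expect_equal(row$derivative, want, tolerance = 1e-6)
  }
})

test_that("parameters of d-separated nodes have exactly zero derivative", {
  chain <- bbn(
    nodes = list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2")),
    arcs = list(c("A", "B"), c("B", "C")),
    cpts = list(
      A = list(parents = character(0), prob = c(0.3, 0.7)),
      B = list(parents = "A", prob = matrix(c(0.8, 0.2, 0.4, 0.6), 2)),
      C = list(parents = "B", prob = matrix(c(0.9, 0.1, 0.3, 0.7), 2))
    )
  )
  # given B, C's posterior is independent of A's prior
  rep <- sensitivity_analysis(chain, "C", evidence = c(B = "b1"), nodes = "A")
  expect_true(all(rep$parameters$derivative == 0))
})

test_that("state-wise derivatives sum to zero under proportional covariation", {
  net <- random_bbn(11, max_nodes = 5, max_states = 3)
  target <- names(net$nodes)[1]
  rep <- sensitivity_analysis(net, target)
  sums <- tapply(rep$parameters$derivative,
                 paste(rep$parameters$node, rep$parameters$parent_combo,
                       rep$parameters$state),
                 sum)
  expect_true(all(abs(sums) < 1e-8))
  expect_error(sensitivity_analysis(net, target,
                                    evidence = stats::setNames(
                                      net$nodes[[target]]$states[1], target)),
               "part of the evidence")
})

test_that("cross-validation scores a deterministic relation perfectly", {
  set.seed(5)
  x <- sample(c("x1", "x2"), 60, replace = TRUE)
  rec <- data.frame(X = x, Y = ifelse(x == "x1", "y1", "y2"),
                    stringsAsFactors = FALSE)
  cv <- kfold_cv(copy_net(0.5), rec, k = 5, node = "Y", alpha = 1, seed = 2)
  expect_equal(cv$folds$accuracy, rep(1, 5))
  expect_equal(cv$mean_accuracy, 1)
})

test_that("folds partition the records into near-equal parts, reproducibly", {
  rec <- data.frame(X = rep(c("x1", "x2"), 5), Y = rep(c("y1", "y2"), 5),
                    stringsAsFactors = FALSE)
  cv <- kfold_cv(copy_net(0.5), rec, k = 10, node = "Y", alpha = 1, seed = 3)
  expect_equal(cv$folds$n_test, rep(1L, 10))
  cv2 <- kfold_cv(copy_net(0.5), rec, k = 10, node = "Y", alpha = 1, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(copy_net(0.5), rec, k = 1, node = "Y"), "at least 2")
  expect_error(kfold_cv(copy_net(0.5), rec, k = 11, node = "Y"), "exceeds")
})

test_that("scenario comparison reproduces priors and respects d-separation", {
  net <- learn_cpts(build_network(),
                    discretize_records(
                      generate_grid(default_generator_config(n = 2000, seed = 4)),
                      matrix = default_generator_config(n = 1, seed = 1)$matrix),
                    nodes = observed_nodes(), alpha = 1)
  sc <- scenario_compare(net, list(Geest = c(landscape_type = "Geest")),
                         query = c("soil_texture", "landscape_type"))
  base <- sc$posteriors[sc$posteriors$scenario == "baseline" &
                        sc$posteriors$node == "soil_texture", ]
  prior <- infer_posterior(net, "soil_texture")[[1]]
  expect_equal(base$probability, as.numeric(prior), tolerance = 1e-12)
  geest_sand <- sc$posteriors[sc$posteriors$scenario == "Geest" &
                              sc$posteriors$node == "soil_texture" &
                              sc$posteriors$state == "sand", "probability"]
  base_sand <- base[base$state == "sand", "probability"]
  expect_gt(geest_sand, base_sand)
  expect_equal(nrow(sc$arc_strengths), nrow(net$arcs))
})
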