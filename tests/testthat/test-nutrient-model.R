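# The 14-node model: catalogue, discretization, lookup and
# classification rules, expert CPT heuristics.

toy_matrix <- es_matrix(c("312" = 4, "231" = 0, "211" = 1))

test_that("the default build has 14 nodes, the published states, and is acyclic", {
  net <- build_network()
  expect_length(net$nodes, 14L)
  expect_true(validate_bbn(net)$ok)
  expect_identical(node_states(net, "demand"), c("low", "medium", "high"))
  expect_identical(node_states(net, "preliminary_potential"),
                   c("P_no", "P_1", "P_2", "P_3", "P_4", "P_5"))
  expect_identical(node_states(net, "soil_texture"),
                   c("sand", "peat", "silt_clay", "other"))
  expect_identical(node_states(net, "budget"), c("sustainable", "unsustainable"))
})

test_that("continuous variables discretize per the published thresholds", {
  n <- 12
  rec <- data.frame(
    cell_id = seq_len(n),
    landscape_type = "Geest", lulc_class = "312",
    slope = c(0.1, 0.2039, 0.3, 0.6581, 0.7, rep(0.1, n - 5)),
    field_capacity = c(rep(250, 5), 150, 200, 300, 310, rep(250, n - 9)),
    nutrient_availability = c(rep(400, 9), 300, 600, 601),
    soil_texture = "sand", wind_erosion = "no", water_erosion = "no",
    nitrate_leaching = "low",
    nitrogen_surplus = 50,
    stringsAsFactors = FALSE
  )
  st <- discretize_records(rec, matrix = toy_matrix)
  # slope: right-closed classes with breaks 0.2039 / 0.6581 degrees
  expect_identical(st$slope[1:5], c("low", "low", "medium", "medium", "high"))
  # field capacity: < 200 / 200-300 / > 300 mm, both boundaries medium
  expect_identical(st$field_capacity[6:9], c("low", "medium", "medium", "high"))
  # nutrient availability: < 300 / 300-600 / > 600 kmol_c/ha
  expect_identical(st$natural_nutrient_availability[10:12],
                   c("medium", "medium", "high"))
  expect_identical(unique(st$preliminary_potential), "P_4")
})

test_that("nitrogen surplus maps to demand with <=40 / 41-60 / >60 closure", {
  rec <- data.frame(
    cell_id = 1:5, landscape_type = "Marsch", lulc_class = "211",
    slope = 0.1, field_capacity = 250, nutrient_availability = 400,
    soil_texture = "silt_clay", wind_erosion = "no", water_erosion = "no",
    nitrate_leaching = "low",
    nitrogen_surplus = c(-5, 40, 41, 60, 70),
    stringsAsFactors = FALSE
  )
  st <- discretize_records(rec, matrix = toy_matrix)
  expect_identical(st$demand, c("low", "low", "medium", "medium", "high"))
})

test_that("discretization rejects out-of-domain and unknown values", {
  base <- data.frame(
    cell_id = 1, landscape_type = "Geest", lulc_class = "312", slope = 0.1,
    field_capacity = 250, nutrient_availability = 400, soil_texture = "sand",
    wind_erosion = "no", water_erosion = "no", nitrate_leaching = "low",
    nitrogen_surplus = 50, stringsAsFactors = FALSE
  )
  bad <- base; bad$slope <- -1
  expect_error(discretize_records(bad, matrix = toy_matrix), "slope")
  bad <- base; bad$lulc_class <- "999"
  expect_error(discretize_records(bad, matrix = toy_matrix), "999")
  bad <- base; bad$soil_texture <- "gravel"
  expect_error(discretize_records(bad, matrix = toy_matrix), "soil_texture")
})

test_that("quantile breaks follow the order-statistic rule", {
  expect_equal(quantile_breaks(1:9, 3), c(3, 6))
  expect_equal(quantile_breaks(sample(1:4), 2), 2)
  expect_error(quantile_breaks(rep(1, 10), 3), "distinct")
})

test_that("ES-matrix lookup maps scores to potential states and rejects unknowns", {
  expect_equal(lookup_preliminary_potential("312", toy_matrix), "P_4")
  expect_equal(lookup_preliminary_potential("231", toy_matrix), "P_no")
  expect_error(lookup_preliminary_potential("100", toy_matrix), "unknown LULC")
  expect_error(es_matrix(c("1" = 7)), "0..5")
})

test_that("reclassification and budget truth tables match the documented rules", {
  expect_identical(
    reclassify_potential(c("P_no", "P_1", "P_2", "P_3", "P_4", "P_5")),
    c("low", "low", "medium", "medium", "high", "high"))
  expect_error(reclassify_potential("P_9"), "unknown potential")

  lmh <- c("low", "medium", "high")
  combos <- expand.grid(potential = lmh, demand = lmh, stringsAsFactors = FALSE)
  got <- budget_state(combos$potential, combos$demand)
  rank <- function(x) match(x, lmh)
  want <- ifelse(rank(combos$potential) >= rank(combos$demand),
                 "sustainable", "unsustainable")  # default tie: sustainable
  expect_identical(got, want)
  # configurable tie rule
  expect_identical(budget_state("medium", "medium", tie = "unsustainable"),
                   "unsustainable")
  expect_identical(budget_state("high", "low"), "sustainable")
  expect_identical(budget_state("low", "high"), "unsustainable")
})

test_that("expert CPTs are normalized, peaked and ordinal-consistent", {
  net <- build_network()
  for (nm in expert_nodes()) {
    prob <- net$cpts[[nm]]$prob
    cols <- matrix(prob, nrow = dim(prob)[1])
    expect_true(all(abs(colSums(cols) - 1) < 1e-9))
  }
  # erosion column for (wind high, water no) peaks on high
  er <- net$cpts$erosion$prob
  expect_equal(which.max(er[, 4, 1]), 3L)
  # neutral-score column peaks at the preliminary state with mass < 1
  # (fc medium, nna medium, leaching medium, erosion medium, prelim P_1)
  pot <- net$cpts$nutrient_regulation_potential$prob
  col <- pot[, 2, 2, 2, 2, 2]
  expect_equal(which.max(col), 2L)
  expect_lt(max(col), 1)
  expect_error(default_expert_cpt("slope"), "not an expert node")
})

test_that("expected potential rank is non-decreasing in the favourability score", {
  pot <- build_network()$cpts$nutrient_regulation_potential$prob
  ranks <- 0:5
  for (pp in 1:6) {
    # walk score upward via (fc, nna) with leaching/erosion fixed low
    escore <- sapply(1:3, function(fc) sum(pot[, fc, fc, 1, 1, pp] * ranks))
    expect_true(all(diff(escore) >= -1e-12))
  }
})

test_that("deterministic nodes encode point-mass columns", {
  net <- build_network()
  rc <- matrix(net$cpts$reclassified_potential$prob, nrow = 3)
  expect_true(all(colSums(rc == 1) == 1))
  bg <- matrix(net$cpts$budget$prob, nrow = 2)
  expect_true(all(colSums(bg == 1) == 1))
})
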