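# The 14-node nutrient-regulation (nitrogen) ecosystem-service model:
# node/state catalogue, default DAG, discretization scheme, ES-matrix
# lookup, reclassification and budget rules, and the expert CPT heuristics
# for the four manually specified nodes.

POTENTIAL_STATES <- c("P_no", "P_1", "P_2", "P_3", "P_4", "P_5")
LMH <- c("low", "medium", "high")
EROSION4 <- c("no", "low", "medium", "high")

#' Node and state catalogue of the nutrient-regulation model
#'
#' The model has 14 discrete nodes: landscape type (Huegelland, Geest,
#' Marsch), soil texture, slope, field capacity, wind and water erosion,
#' natural nutrient availability, nitrate leaching potential, overall
#' erosion, preliminary and modelled nutrient-regulation ES potential
#' (six ordinal classes P_no..P_5), the reclassified potential, the demand
#' (indexed by nitrogen surplus) and the supply-demand budget.
#'
#' @return named list of state-label vectors, one per node, in declared
#'   (ordinal where meaningful) order.
#' @export
model_nodes <- function() {
  list(
    landscape_type = c("Huegelland", "Geest", "Marsch"),
    soil_texture = c("sand", "peat", "silt_clay", "other"),
    slope = LMH,
    field_capacity = LMH,
    wind_erosion = EROSION4,
    water_erosion = EROSION4,
    natural_nutrient_availability = LMH,
    nitrate_leaching_potential = LMH,
    erosion = LMH,
    preliminary_potential = POTENTIAL_STATES,
    nutrient_regulation_potential = POTENTIAL_STATES,
    reclassified_potential = LMH,
    demand = LMH,
    budget = c("sustainable", "unsustainable")
  )
}

#' Default arc set of the nutrient-regulation model
#'
#' Landscape type drives the site conditions (soil texture, slope), the
#' land-cover-derived preliminary potential and the demand; soil texture
#' drives field capacity, natural nutrient availability, nitrate leaching
#' and wind erosion; slope drives water erosion; wind and water erosion
#' combine into overall erosion; the site variables and the preliminary
#' potential determine the modelled potential, which is reclassified and
#' balanced against the demand in the budget node. The arc set is
#' configurable: [build_network()] accepts any acyclic replacement.
#'
#' @return two-column character matrix of (parent, child) arcs.
#' @export
model_arcs <- function() {
  arcs <- rbind(
    c("landscape_type", "soil_texture"),
    c("landscape_type", "slope"),
    c("landscape_type", "preliminary_potential"),
    c("landscape_type", "demand"),
    c("soil_texture", "field_capacity"),
    c("soil_texture", "natural_nutrient_availability"),
    c("soil_texture", "nitrate_leaching_potential"),
    c("soil_texture", "wind_erosion"),
    c("slope", "water_erosion"),
    c("wind_erosion", "erosion"),
    c("water_erosion", "erosion"),
    c("field_capacity", "nutrient_regulation_potential"),
    c("natural_nutrient_availability", "nutrient_regulation_potential"),
    c("nitrate_leaching_potential", "nutrient_regulation_potential"),
    c("erosion", "nutrient_regulation_potential"),
    c("preliminary_potential", "nutrient_regulation_potential"),
    c("nutrient_regulation_potential", "reclassified_potential"),
    c("reclassified_potential", "budget"),
    c("demand", "budget")
  )
  colnames(arcs) <- c("parent", "child")
  arcs
}

#' Nodes whose CPTs are expert-specified rather than learned
#'
#' @return character vector of the four expert nodes.
#' @export
expert_nodes <- function() {
  c("erosion", "nutrient_regulation_potential", "reclassified_potential", "budget")
}

#' Observed (data-backed) nodes of the model
#'
#' The ten nodes whose states are read off the grid data after
#' discretization; their CPTs are learned by maximum likelihood.
#'
#' @return character vector of node names.
#' @export
observed_nodes <- function() {
  setdiff(names(model_nodes()), expert_nodes())
}

# ---- discretization ------------------------------------------------------

#' Default discretization scheme for the continuous grid variables
#'
#' Three-class schemes with the published thresholds: field capacity
#' < 200 / 200-300 / > 300 mm; natural nutrient availability < 300 /
#' 300-600 / > 600 kmol_c/ha; nitrogen surplus (demand) <= 40 / 41-60 /
#' > 60 kg N/ha; slope quantile classes with default breaks 0.2039 and
#' 0.6581 degrees. Interval closure: for the "middle-closed" style
#' (field capacity, nutrient availability) the middle class includes both
#' breakpoints; for the "right-closed" style (surplus, slope) each class
#' includes its upper breakpoint. Every boundary value therefore belongs
#' to exactly one class.
#'
#' @param slope_breaks numeric length-2 vector of slope class breaks in
#'   degrees; replace with [quantile_breaks()] output to recalibrate on a
#'   study area.
#' @return a `discretization_scheme`: named list of per-variable rules.
#' @export
default_discretization <- function(slope_breaks = c(0.2039, 0.6581)) {
  structure(list(
    field_capacity = list(breaks = c(200, 300), labels = LMH,
                          style = "middle_closed", domain = c(0, Inf)),
    natural_nutrient_availability = list(breaks = c(300, 600), labels = LMH,
                                         style = "middle_closed", domain = c(0, Inf)),
    nitrogen_surplus = list(breaks = c(40, 60), labels = LMH,
                            style = "right_closed", domain = c(-Inf, Inf)),
    slope = list(breaks = slope_breaks, labels = LMH,
                 style = "right_closed", domain = c(0, Inf)),
    categorical = list(
      landscape_type = c("Huegelland", "Geest", "Marsch"),
      soil_texture = c("sand", "peat", "silt_clay", "other"),
      wind_erosion = EROSION4,
      water_erosion = EROSION4,
      nitrate_leaching_potential = LMH
    )
  ), class = "discretization_scheme")
}

# classify a numeric vector into the 3 classes of one scheme entry
.classify3 <- function(x, rule, varname) {
  bad <- !is.finite(x) | x < rule$domain[1L] | x > rule$domain[2L]
  if (any(bad))
    stop(sprintf("%s: value(s) outside the declared domain (rows %s)",
                 varname, paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  b <- rule$breaks
  cls <- if (rule$style == "middle_closed") {
    ifelse(x < b[1L], 1L, ifelse(x <= b[2L], 2L, 3L))
  } else {  # right_closed
    ifelse(x <= b[1L], 1L, ifelse(x <= b[2L], 2L, 3L))
  }
  rule$labels[cls]
}

#' Quantile class breaks
#'
#' Break k (k = 1..n_classes-1) is the ceiling(k * n / n_classes)-th order
#' statistic of the values — a deterministic, order-independent rule.
#'
#' @param values numeric vector.
#' @param n_classes integer >= 2.
#' @return numeric vector of n_classes - 1 breaks.
#' @export
quantile_breaks <- function(values, n_classes) {
  stopifnot(n_classes >= 2L)
  values <- values[is.finite(values)]
  n <- length(values)
  if (length(unique(values)) < n_classes)
    stop("fewer distinct values than classes", call. = FALSE)
  s <- sort(values)
  idx <- ceiling(seq_len(n_classes - 1L) * n / n_classes)
  s[idx]
}

#' Look up the preliminary ES potential for a land-cover class
#'
#' The ES matrix assigns each land-use/land-cover (LULC) class code an
#' integer nutrient-regulation potential score from 0 (no relevant
#' potential) to 5 (highest potential); score 0 maps to state `P_no`,
#' score s > 0 to `P_s`.
#'
#' @param lulc integer/character LULC class code(s).
#' @param matrix named integer vector: names are class codes, values
#'   scores in 0..5 (see [es_matrix()]).
#' @return character vector of potential states.
#' @export
lookup_preliminary_potential <- function(lulc, matrix) {
  key <- as.character(lulc)
  miss <- !(key %in% names(matrix))
  if (any(miss))
    stop("unknown LULC class code(s): ",
         paste(unique(key[miss]), collapse = ", "), call. = FALSE)
  s <- as.integer(matrix[key])
  ifelse(s == 0L, "P_no", paste0("P_", s))
}

#' Construct an ES-matrix lookup table
#'
#' @param scores named numeric vector or list, LULC class code -> score in
#'   0..5. The package ships no default scores: the per-class values come
#'   from a separate ES-matrix publication and must be supplied (the
#'   synthetic-data generator carries its own toy table).
#' @return validated named integer vector of class `es_matrix`.
#' @export
es_matrix <- function(scores) {
  s <- unlist(scores)
  if (is.null(names(s)) || any(names(s) == ""))
    stop("ES matrix scores must be named by LULC class code", call. = FALSE)
  if (anyDuplicated(names(s)))
    stop("duplicate LULC class codes in ES matrix", call. = FALSE)
  if (any(s < 0 | s > 5 | s != round(s)))
    stop("ES matrix scores must be integers in 0..5", call. = FALSE)
  structure(stats::setNames(as.integer(s), names(s)), class = "es_matrix")
}

#' Reclassify a six-level potential into low/medium/high
#'
#' Default mapping: P_no and P_1 -> low, P_2 and P_3 -> medium, P_4 and
#' P_5 -> high. The mapping is configurable.
#'
#' @param p character vector of potential states (P_no..P_5).
#' @param mapping named character vector, potential state -> low/medium/high.
#' @return character vector of reclassified states.
#' @export
reclassify_potential <- function(p, mapping = default_reclassification()) {
  bad <- !(p %in% names(mapping))
  if (any(bad))
    stop("unknown potential state(s): ", paste(unique(p[bad]), collapse = ", "),
         call. = FALSE)
  unname(mapping[p])
}

#' @rdname reclassify_potential
#' @export
default_reclassification <- function() {
  c(P_no = "low", P_1 = "low", P_2 = "medium", P_3 = "medium",
    P_4 = "high", P_5 = "high")
}

#' Supply-demand budget rule
#'
#' The budget is sustainable when the (reclassified) potential exceeds the
#' demand on the common low < medium < high ordinal scale. Equality is not
#' covered by the higher/lower dichotomy; the tie rule is explicit and
#' defaults to "sustainable".
#'
#' @param potential,demand character vectors of states low/medium/high.
#' @param tie one of "sustainable" or "unsustainable": the budget state
#'   assigned when potential and demand ranks are equal.
#' @return character vector, "sustainable" or "unsustainable".
#' @export
budget_state <- function(potential, demand, tie = c("sustainable", "unsustainable")) {
  tie <- match.arg(tie)
  rp <- match(potential, LMH)
  rd <- match(demand, LMH)
  if (anyNA(rp) || anyNA(rd))
    stop("potential and demand must be low/medium/high", call. = FALSE)
  ifelse(rp > rd, "sustainable", ifelse(rp < rd, "unsustainable", tie))
}

#' Discretize raw grid records into model state assignments
#'
#' Maps each grid cell's measurements onto the states of the ten observed
#' nodes: continuous variables through the discretization scheme, the LULC
#' code through the ES matrix into the preliminary potential, nitrogen
#' surplus into the demand class, and categorical variables validated
#' against their vocabularies.
#'
#' @param records data frame of grid records (see [read_grid_csv()] for
#'   the canonical columns).
#' @param scheme a discretization scheme, see [default_discretization()].
#' @param matrix an [es_matrix()] table.
#' @return data frame with columns `cell_id`, `x`, `y` (passed through
#'   when present) and one character column per observed node.
#' @export
discretize_records <- function(records, scheme = default_discretization(),
                               matrix) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  for (v in names(scheme$categorical)) {
    bad <- !(records[[v]] %in% scheme$categorical[[v]])
    if (any(bad))
      stop(sprintf("%s: unknown categorical level(s) %s (rows %s)", v,
                   paste(unique(records[[v]][bad]), collapse = ", "),
                   paste(utils::head(which(bad), 5L), collapse = ", ")),
           call. = FALSE)
  }
  neg <- c("slope", "field_capacity", "nutrient_availability")
  for (v in neg) {
    if (any(records[[v]] < 0, na.rm = TRUE))
      stop(sprintf("%s: negative values are outside the declared domain", v),
           call. = FALSE)
  }
  out <- data.frame(
    landscape_type = as.character(records$landscape_type),
    soil_texture = as.character(records$soil_texture),
    slope = .classify3(records$slope, scheme$slope, "slope"),
    field_capacity = .classify3(records$field_capacity, scheme$field_capacity,
                                "field_capacity"),
    wind_erosion = as.character(records$wind_erosion),
    water_erosion = as.character(records$water_erosion),
    natural_nutrient_availability = .classify3(
      records$nutrient_availability, scheme$natural_nutrient_availability,
      "nutrient_availability"),
    nitrate_leaching_potential = as.character(records$nitrate_leaching),
    preliminary_potential = lookup_preliminary_potential(records$lulc_class, matrix),
    demand = .classify3(records$nitrogen_surplus, scheme$nitrogen_surplus,
                        "nitrogen_surplus"),
    stringsAsFactors = FALSE
  )
  keep <- intersect(c("cell_id", "x", "y"), names(records))
  cbind(records[keep], out)
}

# ---- expert CPTs ---------------------------------------------------------

# spread `peak_mass` on state index `center`, `side_mass` on each direct
# neighbour, clip to 1..n and renormalize
.peaked_column <- function(n, center, peak_mass, side_mass) {
  p <- numeric(n)
  p[center] <- peak_mass
  if (center > 1L) p[center - 1L] <- side_mass
  if (center < n) p[center + 1L] <- side_mass
  p / sum(p)
}

#' Default expert-elicited CPTs
#'
#' Four nodes carry manually specified (not learned) CPTs, generated by
#' documented heuristics:
#' \itemize{
#'   \item `erosion`: the ordinal maximum of wind and water erosion
#'     (no/low -> low, medium -> medium, high -> high) receives mass 0.7
#'     with 0.15 on each neighbouring class (clipped and renormalized);
#'   \item `nutrient_regulation_potential`: the preliminary potential is
#'     shifted by -1/0/+1 according to a site-favourability score — the sum
#'     of the ordinal ranks (1..3) of field capacity and natural nutrient
#'     availability minus those of nitrate leaching and erosion — with
#'     mass 0.5 on the shifted state and 0.25 on each neighbour, so the
#'     conditional peaks at (a shift of) the preliminary state with
#'     less-than-certain mass;
#'   \item `reclassified_potential` and `budget`: deterministic point-mass
#'     encodings of [reclassify_potential()] and [budget_state()].
#' }
#'
#' @param node one of the [expert_nodes()].
#' @param params list of heuristic parameters: `shift_down` / `shift_up`
#'   (score thresholds for the -1 / +1 potential shift; defaults -2 and 2),
#'   `reclassification` (see [default_reclassification()]), `tie` (budget
#'   tie rule), `erosion_peak` / `erosion_side`, `potential_peak` /
#'   `potential_side` mass parameters.
#' @return list with elements `parents` and `prob` suitable for [bbn()].
#' @export
default_expert_cpt <- function(node, params = list()) {
  p <- utils::modifyList(list(
    shift_down = -2, shift_up = 2,
    reclassification = default_reclassification(),
    tie = "sustainable",
    erosion_peak = 0.7, erosion_side = 0.15,
    potential_peak = 0.5, potential_side = 0.25
  ), params)
  nodes <- model_nodes()
  switch(node,
    erosion = {
      # parents: wind_erosion, water_erosion (4 states each)
      prob <- array(0, dim = c(3L, 4L, 4L))
      for (w in 1:4) for (a in 1:4) {
        m <- max(w, a) - 1L            # 0..3 on the no/low/medium/high scale
        center <- c(1L, 1L, 2L, 3L)[m + 1L]
        prob[, w, a] <- .peaked_column(3L, center, p$erosion_peak, p$erosion_side)
      }
      list(parents = c("wind_erosion", "water_erosion"), prob = prob)
    },
    nutrient_regulation_potential = {
      parents <- c("field_capacity", "natural_nutrient_availability",
                   "nitrate_leaching_potential", "erosion", "preliminary_potential")
      prob <- array(0, dim = c(6L, 3L, 3L, 3L, 3L, 6L))
      for (fc in 1:3) for (na in 1:3) for (le in 1:3) for (er in 1:3)
        for (pp in 1:6) {
          score <- fc + na - le - er
          shift <- if (score <= p$shift_down) -1L
                   else if (score >= p$shift_up) 1L else 0L
          center <- min(max(pp + shift, 1L), 6L)
          prob[, fc, na, le, er, pp] <-
            .peaked_column(6L, center, p$potential_peak, p$potential_side)
        }
      list(parents = parents, prob = prob)
    },
    reclassified_potential = {
      prob <- array(0, dim = c(3L, 6L))
      for (j in 1:6) {
        cls <- reclassify_potential(POTENTIAL_STATES[j], p$reclassification)
        prob[match(cls, LMH), j] <- 1
      }
      list(parents = "nutrient_regulation_potential", prob = prob)
    },
    budget = {
      prob <- array(0, dim = c(2L, 3L, 3L))
      for (rp in 1:3) for (d in 1:3) {
        b <- budget_state(LMH[rp], LMH[d], tie = p$tie)
        prob[match(b, c("sustainable", "unsustainable")), rp, d] <- 1
      }
      list(parents = c("reclassified_potential", "demand"), prob = prob)
    },
    stop(sprintf("'%s' is not an expert node", node), call. = FALSE)
  )
}

#' Build the 14-node nutrient-regulation network
#'
#' Assembles the model with its default (configurable) DAG, the Table-style
#' state catalogue, expert CPTs for the four expert nodes and either
#' supplied learned CPTs or uniform placeholder CPTs for the remaining ten
#' nodes (placeholders are replaced by [learn_cpts()]).
#'
#' @param expert_params parameter list passed to [default_expert_cpt()].
#' @param learned_cpts optional named list of CPTs (elements `parents`,
#'   `prob`) for non-expert nodes.
#' @param arcs arc matrix, defaulting to [model_arcs()].
#' @param expert which nodes are expert-specified (default [expert_nodes()]).
#' @return a validated [bbn] object.
#' @export
build_network <- function(expert_params = list(), learned_cpts = NULL,
                          arcs = model_arcs(), expert = expert_nodes()) {
  nodes <- model_nodes()
  ranks <- list(
    slope = 1:3, field_capacity = 1:3, natural_nutrient_availability = 1:3,
    nitrate_leaching_potential = 1:3, erosion = 1:3,
    wind_erosion = 0:3, water_erosion = 0:3,
    preliminary_potential = 0:5, nutrient_regulation_potential = 0:5,
    reclassified_potential = 1:3, demand = 1:3
  )
  nodes <- stats::setNames(lapply(names(nodes), function(nm)
    list(states = nodes[[nm]], ordinal = ranks[[nm]])), names(nodes))
  cpts <- list()
  for (nm in names(nodes)) {
    if (nm %in% expert) {
      cpts[[nm]] <- default_expert_cpt(nm, expert_params)
    } else if (!is.null(learned_cpts[[nm]])) {
      cpts[[nm]] <- learned_cpts[[nm]]
    } else {
      parents <- arcs[arcs[, "child"] == nm, "parent"]
      card <- c(length(nodes[[nm]]$states),
                vapply(parents, function(p) length(nodes[[p]]$states), integer(1L)))
      cpts[[nm]] <- list(parents = parents,
                         prob = array(1 / card[1L], dim = card))
    }
  }
  net <- bbn(nodes = nodes, arcs = arcs, cpts = cpts)
  chk <- validate_bbn(net)
  if (!chk$ok)
    stop("invalid model configuration: ", paste(chk$violations, collapse = "; "),
         call. = FALSE)
  net
}
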