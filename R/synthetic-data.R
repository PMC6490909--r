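# Seeded synthetic landscape-grid generator. Emulates the qualitative
# structure of the Schleswig-Holstein landscapes: Geest cells are
# sand-dominated with poorer, leaching-prone soils and elevated wind
# erosion; Huegelland and Marsch are silt/clay-dominated; the Marsch is
# flat while the Huegelland is hilly; slope drives water erosion; nitrogen
# surplus (the demand indicator) is landscape-conditioned. The generating
# probabilities are package fixtures chosen for realistic orderings, not
# values calibrated to any published map.

LANDSCAPES <- c("Huegelland", "Geest", "Marsch")

.norm_cols <- function(m) {
  ok <- abs(colSums(m) - 1) <= 1e-9
  all(ok)
}

#' Build and validate a synthetic-grid generator configuration
#'
#' @param n number of grid cells.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param landscape_props named probability vector over Huegelland, Geest,
#'   Marsch (entries may be 0).
#' @param tables named list of generating conditional tables (child states
#'   in rows, parent states in columns, columns summing to 1):
#'   `soil_texture`, `slope_class`, `lulc` (conditioned on landscape),
#'   `field_capacity_class`, `nutrient_availability_class`,
#'   `nitrate_leaching`, `wind_erosion` (conditioned on soil texture),
#'   `water_erosion` (conditioned on slope class), `surplus_class`
#'   (conditioned on landscape).
#' @param emission named list of per-class continuous emission ranges
#'   (`slope` degrees, `field_capacity` mm, `nutrient_availability`
#'   kmol_c/ha, `nitrogen_surplus` kg N/ha); each range must lie inside
#'   the discretization interval of its class so that discretizing a
#'   generated record returns exactly the sampled class.
#' @param matrix the [es_matrix()] used to score the synthetic LULC codes.
#' @param spacing grid spacing in metres for the cosmetic row-major cell
#'   coordinates.
#' @param scheme discretization scheme the emission ranges are checked
#'   against.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n, seed, landscape_props, tables, emission,
                             matrix, spacing = 200,
                             scheme = default_discretization()) {
  cfg <- structure(list(n = as.integer(n), seed = as.integer(seed),
                        landscape_props = landscape_props, tables = tables,
                        emission = emission, matrix = matrix,
                        spacing = spacing, scheme = scheme),
                   class = "generator_config")
  if (cfg$n < 1L) stop("n must be positive", call. = FALSE)
  if (abs(sum(landscape_props) - 1) > 1e-9 || any(landscape_props < 0))
    stop("landscape proportions must be a probability vector", call. = FALSE)
  if (!setequal(names(landscape_props), LANDSCAPES))
    stop("landscape proportions must name Huegelland, Geest, Marsch", call. = FALSE)
  for (tn in names(tables)) {
    tab <- tables[[tn]]
    if (any(tab < 0) || !.norm_cols(tab))
      stop(sprintf("generating table '%s': columns must sum to 1", tn),
           call. = FALSE)
  }
  emvar <- c(slope = "slope", field_capacity = "field_capacity",
             nutrient_availability = "natural_nutrient_availability",
             nitrogen_surplus = "nitrogen_surplus")
  for (v in names(emvar)) {
    rule <- scheme[[emvar[[v]]]]
    for (cls in names(emission[[v]])) {
      rng <- emission[[v]][[cls]]
      if (length(rng) != 2L || rng[1L] > rng[2L])
        stop(sprintf("emission range for %s/%s is empty", v, cls), call. = FALSE)
      got <- unique(.classify3(rng, rule, v))
      if (!identical(got, cls))
        stop(sprintf("emission range for %s/%s is not nested in its class interval",
                     v, cls), call. = FALSE)
    }
  }
  cfg
}

#' Default generator configuration for a study region
#'
#' `"schleswig-holstein"` uses all three landscape types; `"bornhoeved"`
#' (the local-scale lakes district) sets the Marsch proportion to zero and
#' shifts the nitrogen-surplus distribution toward the medium and high
#' classes, reflecting its more agricultural, spatially explicit demand
#' data.
#'
#' @param region `"schleswig-holstein"` or `"bornhoeved"`.
#' @param n number of cells (default 5000).
#' @param seed integer seed (default 1).
#' @return a `generator_config`.
#' @export
default_generator_config <- function(region = c("schleswig-holstein", "bornhoeved"),
                                     n = 5000, seed = 1) {
  region <- match.arg(region)
  textures <- c("sand", "peat", "silt_clay", "other")
  codes <- c("112", "211", "231", "243", "311", "411")
  tab <- function(rows, cols, values)
    matrix(values, nrow = length(rows), dimnames = list(rows, cols))
  tables <- list(
    soil_texture = tab(textures, LANDSCAPES, c(
      0.20, 0.10, 0.60, 0.10,   # Huegelland: silt/clay-dominated moraines
      0.70, 0.15, 0.10, 0.05,   # Geest: sandy outwash plains
      0.05, 0.15, 0.70, 0.10)), # Marsch: marine silt/clay
    slope_class = tab(LMH, LANDSCAPES, c(
      0.15, 0.35, 0.50,         # Huegelland: hilly
      0.40, 0.35, 0.25,
      0.80, 0.15, 0.05)),       # Marsch: flat
    lulc = tab(codes, LANDSCAPES, c(
      0.10, 0.45, 0.20, 0.05, 0.15, 0.05,
      0.10, 0.35, 0.15, 0.10, 0.25, 0.05,
      0.05, 0.30, 0.45, 0.05, 0.05, 0.10)),
    field_capacity_class = tab(LMH, textures, c(
      0.70, 0.25, 0.05,         # sand: low water retention
      0.10, 0.30, 0.60,
      0.15, 0.45, 0.40,
      1 / 3, 1 / 3, 1 / 3)),
    nutrient_availability_class = tab(LMH, textures, c(
      0.70, 0.25, 0.05,
      0.20, 0.50, 0.30,
      0.10, 0.40, 0.50,
      1 / 3, 1 / 3, 1 / 3)),
    nitrate_leaching = tab(LMH, textures, c(
      0.10, 0.25, 0.65,         # sand: leaching-prone
      0.50, 0.35, 0.15,
      0.60, 0.30, 0.10,
      1 / 3, 1 / 3, 1 / 3)),
    wind_erosion = tab(EROSION4, textures, c(
      0.10, 0.20, 0.30, 0.40,   # sand: wind-erodible
      0.30, 0.40, 0.20, 0.10,
      0.50, 0.30, 0.15, 0.05,
      0.40, 0.30, 0.20, 0.10)),
    water_erosion = tab(EROSION4, LMH, c(
      0.70, 0.20, 0.08, 0.02,
      0.30, 0.40, 0.20, 0.10,
      0.05, 0.20, 0.35, 0.40)),
    surplus_class = if (region == "schleswig-holstein") {
      tab(LMH, LANDSCAPES, c(
        0.60, 0.25, 0.15,
        0.30, 0.35, 0.35,       # Geest: above-average demand
        0.50, 0.30, 0.20))
    } else {
      tab(LMH, LANDSCAPES, c(
        0.30, 0.45, 0.25,       # local scale: demand shifted to medium
        0.20, 0.45, 0.35,
        0.50, 0.30, 0.20))
    }
  )
  props <- if (region == "schleswig-holstein") {
    c(Huegelland = 0.40, Geest = 0.45, Marsch = 0.15)
  } else {
    c(Huegelland = 0.55, Geest = 0.45, Marsch = 0)
  }
  emission <- list(
    slope = list(low = c(0, 0.2039), medium = c(0.205, 0.658),
                 high = c(0.66, 13.44)),
    field_capacity = list(low = c(50, 199.9), medium = c(200, 300),
                          high = c(301, 450)),
    nutrient_availability = list(low = c(50, 299.9), medium = c(300, 600),
                                 high = c(601, 900)),
    nitrogen_surplus = list(low = c(-20, 40), medium = c(40.5, 60),
                            high = c(60.5, 120))
  )
  # toy ES matrix for the synthetic LULC codes (urban 0, arable 1,
  # pasture 2, heterogeneous agriculture 3, forest 4, wetland 5)
  m <- es_matrix(c("112" = 0, "211" = 1, "231" = 2, "243" = 3,
                   "311" = 4, "411" = 5))
  generator_config(n = n, seed = seed, landscape_props = props,
                   tables = tables, emission = emission, matrix = m)
}

# sample child states conditionally on a vector of parent states
.sample_cond <- function(tab, parent_vals) {
  out <- character(length(parent_vals))
  for (ps in colnames(tab)) {
    i <- which(parent_vals == ps)
    if (length(i))
      out[i] <- sample(rownames(tab), length(i), replace = TRUE,
                       prob = tab[, ps])
  }
  out
}

# draw uniform within the emission range of each sampled class
.emit <- function(ranges, classes) {
  x <- numeric(length(classes))
  for (cls in names(ranges)) {
    i <- which(classes == cls)
    if (length(i))
      x[i] <- stats::runif(length(i), ranges[[cls]][1L], ranges[[cls]][2L])
  }
  x
}

#' Generate a synthetic landscape grid
#'
#' Ancestral sampling through the generating tables: landscape type from
#' the configured proportions, then soil texture, slope class, LULC and
#' surplus class given the landscape, site variables given texture, water
#' erosion given slope; continuous values are drawn uniformly within each
#' class's emission range. Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return data frame of grid records with columns `cell_id`, `x`, `y`,
#'   `landscape_type`, `lulc_class`, `slope`, `field_capacity`,
#'   `nutrient_availability`, `soil_texture`, `wind_erosion`,
#'   `water_erosion`, `nitrate_leaching`, `nitrogen_surplus`.
#' @export
generate_grid <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n
  with_seed(cfg$seed, {
    landscape <- sample(LANDSCAPES, n, replace = TRUE,
                        prob = cfg$landscape_props[LANDSCAPES])
    texture <- .sample_cond(cfg$tables$soil_texture, landscape)
    slope_cls <- .sample_cond(cfg$tables$slope_class, landscape)
    lulc <- .sample_cond(cfg$tables$lulc, landscape)
    fc_cls <- .sample_cond(cfg$tables$field_capacity_class, texture)
    na_cls <- .sample_cond(cfg$tables$nutrient_availability_class, texture)
    leach <- .sample_cond(cfg$tables$nitrate_leaching, texture)
    wind <- .sample_cond(cfg$tables$wind_erosion, texture)
    water <- .sample_cond(cfg$tables$water_erosion, slope_cls)
    surplus_cls <- .sample_cond(cfg$tables$surplus_class, landscape)
    ncol_grid <- ceiling(sqrt(n))
    data.frame(
      cell_id = seq_len(n),
      x = ((seq_len(n) - 1L) %% ncol_grid) * cfg$spacing,
      y = ((seq_len(n) - 1L) %/% ncol_grid) * cfg$spacing,
      landscape_type = landscape,
      lulc_class = lulc,
      slope = .emit(cfg$emission$slope, slope_cls),
      field_capacity = .emit(cfg$emission$field_capacity, fc_cls),
      nutrient_availability = .emit(cfg$emission$nutrient_availability, na_cls),
      soil_texture = texture,
      wind_erosion = wind,
      water_erosion = water,
      nitrate_leaching = leach,
      nitrogen_surplus = .emit(cfg$emission$nitrogen_surplus, surplus_cls),
      stringsAsFactors = FALSE
    )
  })
}

#' Generating CPTs implied by a generator configuration
#'
#' Maps the generating tables onto the model's ten observed nodes, in the
#' model's state order: direct copies for the site variables, the
#' landscape proportions as the landscape prior, the LULC table aggregated
#' through the ES matrix for the preliminary potential, and the surplus
#' class table for the demand. Used to check parameter recovery of
#' [learn_cpts()] against the ground truth.
#'
#' @param cfg a [generator_config()].
#' @return named list of CPTs (elements `parents`, `prob`) for the
#'   observed nodes.
#' @export
implied_model_cpts <- function(cfg) {
  nodes <- model_nodes()
  as_cpt <- function(tab, child, parents) {
    # reorder rows/cols into the model's declared state order
    tab <- tab[nodes[[child]], , drop = FALSE]
    pst <- nodes[[parents]]
    tab <- tab[, pst, drop = FALSE]
    list(parents = parents, prob = array(tab, dim = dim(tab)))
  }
  prelim <- matrix(0, nrow = 6L, ncol = 3L,
                   dimnames = list(POTENTIAL_STATES, LANDSCAPES))
  st <- lookup_preliminary_potential(rownames(cfg$tables$lulc), cfg$matrix)
  for (ls in LANDSCAPES) {
    prelim[, ls] <- vapply(POTENTIAL_STATES, function(s)
      sum(cfg$tables$lulc[st == s, ls]), numeric(1L))
  }
  list(
    landscape_type = list(parents = character(0L),
                          prob = as.numeric(cfg$landscape_props[LANDSCAPES])),
    soil_texture = as_cpt(cfg$tables$soil_texture, "soil_texture", "landscape_type"),
    slope = as_cpt(cfg$tables$slope_class, "slope", "landscape_type"),
    field_capacity = as_cpt(cfg$tables$field_capacity_class,
                            "field_capacity", "soil_texture"),
    natural_nutrient_availability = as_cpt(cfg$tables$nutrient_availability_class,
                                           "natural_nutrient_availability",
                                           "soil_texture"),
    nitrate_leaching_potential = as_cpt(cfg$tables$nitrate_leaching,
                                        "nitrate_leaching_potential",
                                        "soil_texture"),
    wind_erosion = as_cpt(cfg$tables$wind_erosion, "wind_erosion", "soil_texture"),
    water_erosion = as_cpt(cfg$tables$water_erosion, "water_erosion", "slope"),
    preliminary_potential = list(parents = "landscape_type",
                                 prob = array(prelim, dim = dim(prelim))),
    demand = as_cpt(cfg$tables$surplus_class, "demand", "landscape_type")
  )
}
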