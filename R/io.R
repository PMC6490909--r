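# Grid-record IO, run configuration, and the end-to-end pipeline:
# simulate/read -> discretize -> learn -> infer (baseline + scenarios) ->
# sensitivity -> cross-validation, with every artifact written to disk
# and a manifest recording the configuration hash and seed.

GRID_COLUMNS <- c("landscape_type", "lulc_class", "slope", "field_capacity",
                  "nutrient_availability", "soil_texture", "wind_erosion",
                  "water_erosion", "nitrate_leaching", "nitrogen_surplus")
GRID_NUMERIC <- c("slope", "field_capacity", "nutrient_availability",
                  "nitrogen_surplus")

#' Read grid records from a delimited file
#'
#' @param path CSV file, one row per grid cell.
#' @param mapping optional named character vector renaming file headers to
#'   the canonical columns (`canonical = "file header"`), so externally
#'   produced tables can be read without code changes.
#' @return data frame of typed, validated grid records; row numbers are
#'   preserved for error reporting.
#' @export
read_grid_csv <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!(src %in% names(df)))
        stop(sprintf("mapped column '%s' (for '%s') not in file", src, canon),
             call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(GRID_COLUMNS, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (v in intersect(c(GRID_NUMERIC, "x", "y"), names(df))) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- is.na(x) & !is.na(df[[v]]) & df[[v]] != ""
    if (any(bad))
      stop(sprintf("column '%s': unparseable value(s) at row(s) %s", v,
                   paste(utils::head(which(bad), 5L), collapse = ", ")),
           call. = FALSE)
    df[[v]] <- x
  }
  if (!("cell_id" %in% names(df))) df$cell_id <- seq_len(nrow(df))
  df
}

#' Write grid records to CSV
#'
#' @param records data frame of grid records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Returns the full default configuration of [run_pipeline()] as a plain
#' list; user configurations (YAML or JSON, see [read_run_config()]) are
#' merged over these defaults.
#'
#' @return named list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "nutribbn-output",
    grid_csv = NULL,            # when NULL, the generator section is used
    column_mapping = NULL,
    generator = list(region = "schleswig-holstein", n_cells = 5000L),
    discretization = list(slope_breaks = c(0.2039, 0.6581)),
    es_matrix = NULL,           # required when grid_csv is given
    expert = list(),            # overrides for default_expert_cpt()
    learning = list(alpha = 1),
    scenarios = list(Huegelland = c(landscape_type = "Huegelland"),
                     Geest = c(landscape_type = "Geest"),
                     Marsch = c(landscape_type = "Marsch")),
    query = NULL,               # default: all 14 nodes
    sensitivity = list(target = "nutrient_regulation_potential",
                       nodes = NULL),   # default: the ten observed nodes
    cv = list(k = 5L, node = "soil_texture")
  )
}

#' Read a run configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file; entries
#'   override [default_run_config()].
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .merge_config(user)
  # scenario evidence arrives as lists from YAML/JSON; flatten to vectors
  cfg$scenarios <- lapply(cfg$scenarios, unlist)
  if (!is.null(cfg$column_mapping)) cfg$column_mapping <- unlist(cfg$column_mapping)
  cfg
}

# merge a user configuration over the defaults; list-valued sections the
# user supplies replace the default outright instead of being merged into it
.merge_config <- function(user) {
  cfg <- utils::modifyList(default_run_config(), user)
  for (sec in c("scenarios", "query"))
    if (!is.null(user[[sec]])) cfg[[sec]] <- user[[sec]]
  if (!is.null(user$sensitivity) && !is.null(user$sensitivity$nodes))
    cfg$sensitivity$nodes <- user$sensitivity$nodes
  cfg
}

.config_hash <- function(cfg) {
  cfg$output_dir <- NULL  # hash the analysis settings, not the destination
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.stage <- function(label, log, expr) {
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", label, conditionMessage(e)), call. = FALSE))
  out
}

#' Run the full assessment pipeline
#'
#' Executes simulate/read, discretize, learn, baseline and scenario
#' inference, per-cell MAP classification, sensitivity analysis and k-fold
#' cross-validation, writing every artifact under `config$output_dir`:
#' `grid.csv` (when simulated), `states.csv`, `network.json`,
#' `scenarios.csv`, `arc_strengths.csv`, `map_states.csv`,
#' `sensitivity_parameters.csv`, `sensitivity_nodes.csv`, `cv.csv`,
#' `manifest.json` and `log.txt`. Outputs are deterministic given the
#' configuration and seed (the manifest records both).
#'
#' @param config configuration list (see [default_run_config()]) or path
#'   to a YAML/JSON file.
#' @return invisibly, a list with the learned network, the artifact paths
#'   and the in-memory reports.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .merge_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logs <- character(0L)
  note <- function(...) logs <<- c(logs, sprintf(...))
  outp <- function(f) file.path(cfg$output_dir, f)

  # --- input grid ---
  simulated <- is.null(cfg$grid_csv)
  if (simulated) {
    gen <- .stage("simulate", logs, {
      default_generator_config(cfg$generator$region, n = cfg$generator$n_cells,
                               seed = cfg$seed)
    })
    grid <- .stage("simulate", logs, generate_grid(gen))
    write_grid_csv(grid, outp("grid.csv"))
    esm <- gen$matrix
    note("simulate: %d cells for region '%s' (seed %d)", nrow(grid),
         cfg$generator$region, cfg$seed)
  } else {
    grid <- .stage("read", logs, read_grid_csv(cfg$grid_csv, cfg$column_mapping))
    if (is.null(cfg$es_matrix))
      stop("stage 'read': es_matrix must be configured when reading external grids",
           call. = FALSE)
    esm <- es_matrix(cfg$es_matrix)
    note("read: %d cells from %s", nrow(grid), cfg$grid_csv)
  }

  # --- discretize ---
  scheme <- default_discretization(slope_breaks = cfg$discretization$slope_breaks)
  states <- .stage("discretize", logs, discretize_records(grid, scheme, esm))
  utils::write.csv(states, outp("states.csv"), row.names = FALSE, quote = FALSE)
  note("discretize: %d records, 0 dropped", nrow(states))

  # --- learn ---
  net <- .stage("learn", logs, {
    net0 <- build_network(expert_params = cfg$expert)
    learn_cpts(net0, states, nodes = observed_nodes(),
               alpha = cfg$learning$alpha)
  })
  chk <- validate_bbn(net)
  if (!chk$ok)
    stop("stage 'learn': learned network invalid: ",
         paste(chk$violations, collapse = "; "), call. = FALSE)
  write_bbn(net, outp("network.json"))
  note("learn: CPTs for %d nodes (alpha = %g)", length(observed_nodes()),
       cfg$learning$alpha)

  # --- baseline + scenarios ---
  query <- cfg$query %||% node_names(net)
  scen <- .stage("infer", logs, scenario_compare(net, cfg$scenarios, query))
  utils::write.csv(scen$posteriors, outp("scenarios.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(scen$arc_strengths, outp("arc_strengths.csv"),
                   row.names = FALSE, quote = FALSE)
  note("infer: %d scenarios (+ baseline) x %d nodes", length(cfg$scenarios),
       length(query))

  # --- per-cell MAP states of the latent nodes ---
  latent <- setdiff(node_names(net), observed_nodes())
  map_df <- .stage("classify", logs, .map_cells(net, states, latent))
  utils::write.csv(map_df, outp("map_states.csv"), row.names = FALSE,
                   quote = FALSE)
  note("classify: MAP states of %s for %d cells",
       paste(latent, collapse = "/"), nrow(map_df))

  # --- sensitivity ---
  sens_nodes <- cfg$sensitivity$nodes %||% observed_nodes()
  sens <- .stage("sensitivity", logs,
                 sensitivity_analysis(net, cfg$sensitivity$target,
                                      nodes = sens_nodes))
  utils::write.csv(sens$parameters, outp("sensitivity_parameters.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sens$node_aggregate, outp("sensitivity_nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  note("sensitivity: target '%s', %d nodes analysed", cfg$sensitivity$target,
       length(sens_nodes))

  # --- cross-validation ---
  cv <- .stage("crossval", logs,
               kfold_cv(build_network(expert_params = cfg$expert), states,
                        k = cfg$cv$k, node = cfg$cv$node,
                        alpha = cfg$learning$alpha, seed = cfg$seed))
  utils::write.csv(cv$folds, outp("cv.csv"), row.names = FALSE, quote = FALSE)
  note("crossval: k = %d, node '%s', mean accuracy %.4f", cv$k, cv$node,
       cv$mean_accuracy)

  # --- manifest + log ---
  manifest <- list(package = "nutribbn",
                   version = as.character(utils::packageVersion("nutribbn")),
                   seed = cfg$seed, config_hash = .config_hash(cfg),
                   n_cells = nrow(grid), simulated = simulated,
                   artifacts = c("grid.csv", "states.csv", "network.json",
                                 "scenarios.csv", "arc_strengths.csv",
                                 "map_states.csv", "sensitivity_parameters.csv",
                                 "sensitivity_nodes.csv", "cv.csv"))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(logs, outp("log.txt"))
  invisible(list(network = net, config = cfg, scenario = scen,
                 sensitivity = sens, cv = cv, map_states = map_df,
                 output_dir = cfg$output_dir))
}

# MAP states of the latent nodes for every cell, deduplicating identical
# observed-state patterns (one exact inference per unique pattern)
.map_cells <- function(net, states, latent) {
  obs <- intersect(node_names(net), names(states))
  pat <- do.call(paste, c(states[obs], sep = "\r"))
  urows <- which(!duplicated(pat))
  map_u <- matrix(NA_character_, nrow = length(urows), ncol = length(latent),
                  dimnames = list(NULL, latent))
  for (i in seq_along(urows)) {
    ev <- unlist(states[urows[i], obs, drop = FALSE])
    joint <- run_ve(net, latent, ev)
    tot <- sum(joint$values)
    if (tot == 0) stop("impossible evidence in grid row", call. = FALSE)
    for (nd in latent) {
      f <- joint
      for (other in setdiff(latent, nd)) f <- factor_marginalize(f, other)
      map_u[i, nd] <- f$states[[nd]][which.max(f$values)]
    }
  }
  idx <- match(pat, pat[urows])
  out <- as.data.frame(map_u[idx, , drop = FALSE], stringsAsFactors = FALSE)
  keep <- intersect(c("cell_id", "x", "y"), names(states))
  cbind(states[keep], out)
}
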