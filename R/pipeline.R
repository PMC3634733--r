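# Pipeline configuration and the end-to-end driver:
# geometry -> contact -> loads -> solve -> stress -> cervical analysis.

#' Build and validate a pipeline configuration
#'
#' @param geometry named list of [tooth_params()] arguments (without
#'   `wear_depth`, which the wear states control).
#' @param wear_states integer Smith stages (1:3) and/or numeric wear depths
#'   (mm) to simulate, in order; at least one.
#' @param contact list: `epsilon` (mm), `direction` (length 3), `gap_tol`.
#' @param loads list: `total` (N, default 100), `tol` (patch-face matching).
#' @param materials named list of per-region overrides, each `list(E=, nu=)`.
#' @param analysis list: `n_nodes` (cervical sample size, default 10).
#' @param seed integer seed recorded in the manifest and set before the run.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = list(), wear_states = c(1L, 3L),
                            contact = list(), loads = list(),
                            materials = list(), analysis = list(),
                            seed = 1L) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("pipeline_config: unknown key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    }
  }
  check_keys(geometry, setdiff(names(formals(tooth_params)), "wear_depth"),
             "geometry")
  check_keys(contact, c("epsilon", "direction", "gap_tol"), "contact")
  check_keys(loads, c("total", "tol"), "loads")
  check_keys(analysis, c("n_nodes"), "analysis")
  check_keys(materials, REGIONS, "materials")
  for (r in names(materials)) {
    check_keys(materials[[r]], c("E", "nu"), paste0("materials$", r))
  }
  if (!length(wear_states)) stop("pipeline_config: need at least one wear state")
  cfg <- list(
    geometry = geometry,
    wear_states = wear_states,
    contact = utils::modifyList(list(epsilon = 0.05, direction = c(0, -1, 0),
                                     gap_tol = 0.01), contact),
    loads = utils::modifyList(list(total = 100, tol = NULL), loads,
                              keep.null = TRUE),
    materials = materials,
    analysis = utils::modifyList(list(n_nodes = 10L), analysis),
    seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("read_pipeline_config: unknown top-level key(s): ",
         paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

resolve_materials <- function(overrides) {
  mats <- default_materials()
  for (r in names(overrides)) {
    o <- overrides[[r]]
    mats[[r]] <- material(
      E = if (!is.null(o$E)) o$E else mats[[r]]$E,
      nu = if (!is.null(o$nu)) o$nu else mats[[r]]$nu)
  }
  mats
}

# one wear state through the full chain
run_wear_state <- function(params, cfg, materials, label) {
  model <- generate_tooth(params)
  dirn <- cfg$contact$direction
  off <- approach_to_contact(model$crown, model$antagonist, dirn,
                             gap_tol = cfg$contact$gap_tol)
  antag <- translate_surface(model$antagonist,
                             off * dirn / sqrt(sum(dirn^2)))
  contacts <- detect_contact_patches(model$crown, antag,
                                     epsilon = cfg$contact$epsilon)
  if (!length(contacts$patches)) {
    stop("pipeline stage contact [", label, "]: no contact patches detected")
  }
  lc <- build_load_case(model$volume, contacts, model$crown,
                        total = cfg$loads$total, tol = cfg$loads$tol)
  cons <- default_tooth_constraints(model$volume)
  disp <- solve_elastic(model$volume, materials, lc, cons)
  stress <- recover_stress(model$volume, materials, disp)
  sample <- cervical_sigma1(
    sample_cervical_nodes(model$volume, n = cfg$analysis$n_nodes), stress,
    mesh = model$volume)
  zones <- pattern_report(stress, model$volume,
                          root_length = params$root_length)
  list(label = label, params = params, model = model, offset = off,
       contacts = contacts, load_case = lc, displacement = disp,
       stress = stress, sample = sample, zones = zones,
       wear = smith_stage(params))
}

#' Run the full wear-comparison pipeline
#'
#' For each requested wear state: generate the synthetic premolar, bring the
#' antagonist to maximum intercuspation, detect contact patches, build the
#' facet-perpendicular load case (resultant = configured total force), solve
#' the elastic problem, recover stresses, and sample the buccal cervical
#' margin. The least and most worn states are then compared at the homologous
#' nodes. All tabular artifacts plus a run manifest are written to `out_dir`
#' (created if needed); set `write_fields = FALSE` to skip the bulkier
#' surface/volume field files.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param write_fields write STL surfaces and VTU volume fields per state.
#' @return object of class `pipeline_result`: per-state results, the
#'   `wear_comparison`, the config and output paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("toothfem_run_"),
                         write_fields = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geometry
  geom$seed <- config$seed
  base <- do.call(tooth_params, geom)
  depths <- vapply(config$wear_states, function(s) {
    if (is.numeric(s) && s > 0 && s < 1e-6 + 3 && s == round(s)) {
      stage_wear_depth(as.integer(s), base)
    } else as.numeric(s)
  }, numeric(1))
  materials <- resolve_materials(config$materials)
  states <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    label <- sprintf("state%d_wd%.3f", i, depths[i])
    states[[i]] <- run_wear_state(apply_wear(base, depths[i]), config,
                                  materials, label)
  }

  # tables
  cerv <- do.call(rbind, lapply(states, function(st) {
    data.frame(state = st$label, wear_depth = st$params$wear_depth,
               smith_stage = st$wear$stage,
               arc_position = st$sample$arc_position,
               node_id = st$sample$node, sigma1_MPa = st$sample$sigma1)
  }))
  write.csv(cerv, file.path(out_dir, "cervical_sample.csv"), row.names = FALSE)
  zones <- do.call(rbind, lapply(states, function(st) {
    cbind(state = st$label, st$zones)
  }))
  write.csv(zones, file.path(out_dir, "zones.csv"), row.names = FALSE)
  contacts <- do.call(rbind, lapply(states, function(st) {
    cbind(state = st$label, contact_summary(st$contacts))
  }))
  write.csv(contacts, file.path(out_dir, "contact_summary.csv"),
            row.names = FALSE)

  comparison <- compare_wear_states(states[[1]], states[[length(states)]])
  write.csv(comparison$table, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)

  if (write_fields) {
    for (st in states) {
      write_surface(st$model$crown,
                    file.path(out_dir, paste0("crown_", st$label, ".stl")))
      write_surface(st$model$antagonist,
                    file.path(out_dir, paste0("antagonist_", st$label, ".stl")))
      write_volume(st$model$volume,
                   file.path(out_dir, paste0("volume_", st$label, ".vtu")),
                   point_data = list(displacement = st$displacement$u,
                                     sigma1 = st$stress$principal[, 1],
                                     sigma3 = st$stress$principal[, 3]))
    }
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    package = "toothfem",
    version = as.character(utils::packageVersion("toothfem")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    wear_depths = depths,
    states = vapply(states, `[[`, character(1), "label"),
    n_elements = vapply(states, function(st) nrow(st$model$volume$elements),
                        integer(1)),
    n_nodes = vapply(states, function(st) nrow(st$model$volume$nodes),
                     integer(1)),
    total_contact_area = vapply(states, function(st) st$contacts$total_area,
                                numeric(1)),
    load_obliquity_deg = vapply(states, function(st) load_obliquity(st$load_case),
                                numeric(1)),
    mean_cervical_sigma1 = vapply(states, function(st) mean(st$sample$sigma1),
                                  numeric(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(states = states, comparison = comparison, config = config,
                 out_dir = out_dir, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("toothfem pipeline run:", length(x$states), "wear state(s) ->",
      x$out_dir, "\n")
  df <- data.frame(wear_depth = m$wear_depths,
                   contact_area_mm2 = round(m$total_contact_area, 3),
                   obliquity_deg = round(m$load_obliquity_deg, 2),
                   mean_cervical_sigma1_MPa = round(m$mean_cervical_sigma1, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
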