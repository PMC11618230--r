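# Run-configuration reading and schema validation.

.SCHEMA <- list(
  name = "character",
  geometry = list(type = "character", diameter = "numeric", length = "numeric",
                  target_h = "numeric", axial_stretch = "numeric",
                  wall_grading = "numeric",
                  vessel_d = "numeric", aneurysm_d = "numeric",
                  curvature_radius = "numeric", neck_d = "numeric",
                  vessel_length = "numeric"),
  device = list(type = "character", n_wires = "numeric",
                wire_diameter = "numeric", braid_angle = "numeric",
                cell_side = "numeric", center_frac = "numeric",
                length = "numeric", nominal_diameter = "numeric",
                surface_radius = "numeric"),
  flow = list(type = "character", mean_velocity = "numeric",
              flow_rate = "numeric", dp = "numeric"),
  inlet = list(PT = "numeric", AT = "numeric", Fg = "numeric",
               Fg_mg_dl = "numeric"),
  reaction = list(Kwt = "numeric", Kat = "numeric", Kth = "numeric",
                  Km = "numeric", Kss = "numeric", Kwa = "numeric",
                  Kb = "numeric", tau0 = "numeric", r0 = "numeric",
                  n_hill = "numeric", wire_switch_literal = "logical"),
  porosity = list(pi_coeff = "numeric", Cfb0 = "numeric", n_hill = "numeric"),
  fluid = list(rho = "numeric", mu = "numeric"),
  diffusivity = "numeric",
  coupling = list(total_time_target = "numeric", max_coupled_steps = "numeric",
                  eps1 = "numeric", eps2 = "numeric",
                  transport_time_cap = "numeric",
                  checkpoint_every = "numeric"),
  transport = list(courant = "numeric", scheme = "character",
                   rk_stages = "numeric", fiber_length = "numeric",
                   dt_cap = "numeric", wire_shear_delta = "numeric"),
  output = list(dir = "character", cadence = "numeric")
)

#' Read and validate a run configuration file
#'
#' YAML configuration with blocks for geometry, device, flow, inlet
#' concentrations, model constants and numerics. Unknown keys are rejected
#' with their location; known keys are type-checked.
#'
#' @param path a YAML file
#' @return validated configuration list (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .validate_block(cfg, .SCHEMA, "")
  class(cfg) <- "run_config"
  cfg
}

.validate_block <- function(x, schema, where) {
  if (!is.list(x)) stop("config: expected a block at '", where, "'")
  for (key in names(x)) {
    loc <- if (nzchar(where)) paste0(where, ".", key) else key
    if (!key %in% names(schema))
      stop("config: unknown key '", loc, "'")
    spec <- schema[[key]]
    if (is.list(spec)) {
      .validate_block(x[[key]], spec, loc)
    } else {
      ok <- switch(spec,
                   numeric = is.numeric(x[[key]]),
                   character = is.character(x[[key]]),
                   logical = is.logical(x[[key]]))
      if (!ok) stop("config: key '", loc, "' must be ", spec)
    }
  }
  invisible(TRUE)
}
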