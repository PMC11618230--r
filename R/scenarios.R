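#' Build a ready-to-run scenario
#'
#' Reconstructs one of the packaged experiment configurations at a chosen
#' resolution: `tube90` / `tube150` (300 um tube, 1.5 cm/s, 20 um wire
#' screen at 90 / 150 degree cell angle at the midplane), `sidewall_plasma`
#' (4 mm curved vessel, 8 mm sac, 48-wire braided device at 90 degrees,
#' 4 cc/s plasma) and `sidewall_fibrinogen_only` (glass-model variant: wider
#' neck, 5 cm curvature, 20 mm 48x32 um device, fibrinogen concentrate at
#' 330 mg/dl with the thrombin pathway disabled, so only the shear pathway
#' produces fibrin).
#'
#' @param name scenario name or a path to a YAML config
#' @param h_scale multiplies the mesh target element size (> 1 coarsens;
#'   useful for quick runs)
#' @param end_time overrides the simulated global-time target (s)
#' @param overrides nested list merged over the file configuration
#' @param refine_levels wire-adaptive refinement levels for the mesh
#' @return list with `mesh`, `wires`, `ib`, `params` ([model_params]),
#'   `cfg` ([coupling_config]), `config` (the raw validated config)
#' @export
build_scenario <- function(name, h_scale = 1, end_time = NULL,
                           overrides = list(), refine_levels = 0L) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "fdfibrin")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario '", name, "' (no packaged config and no such file)")
  config <- read_run_config(path)
  config <- utils::modifyList(config, overrides)

  g <- config$geometry
  mesh <- switch(g$type,
    tube = generate_tube_mesh(g$diameter, g$length, g$target_h * h_scale,
                              axial_stretch = g$axial_stretch %||% 2,
                              wall_grading = g$wall_grading %||% 1),
    sidewall = generate_sidewall_aneurysm_mesh(
      g$vessel_d, g$aneurysm_d, g$curvature_radius,
      neck_d = g$neck_d %||% g$vessel_d,
      target_h = g$target_h * h_scale,
      vessel_length = g$vessel_length %||% (6 * g$vessel_d)),
    stop("unsupported geometry type '", g$type, "'"))

  d <- config$device
  wires <- if (is.null(d)) NULL else if (d$type == "screen") {
    build_braided_device(n_wires = 0L, wire_diameter = d$wire_diameter,
                         braid_angle = d$braid_angle,
                         surface_radius = g$diameter / 2,
                         type = "screen",
                         center_s = (d$center_frac %||% 0.5) * g$length,
                         cell_side = d$cell_side)
  } else {
    sr <- d$surface_radius %||% (g$vessel_d / 2 - d$wire_diameter / 2)
    full <- build_braided_device(n_wires = d$n_wires,
                                 wire_diameter = d$wire_diameter,
                                 braid_angle = d$braid_angle,
                                 surface_radius = sr,
                                 length = d$length, type = "helical",
                                 curvature_radius = g$curvature_radius,
                                 center_s = 0)
    # keep the orifice-spanning portion: wall-apposed segments live inside
    # the unresolved boundary layer and must not act as cell-thick blockages
    trim_wires_to_orifice(full, mesh$geom$sac_center, mesh$geom$sac_radius,
                          margin = 0.5 * g$target_h * h_scale)
  }
  ib <- compute_immersed_boundary(mesh, wires)
  if (refine_levels > 0L) {
    mesh <- refine_near_wires(mesh, ib, refine_levels, wires)
    ib <- compute_immersed_boundary(mesh, wires)
  }

  # proximity threshold: wire-radius scale, but never below the local mesh
  # size (at coarse resolution the wire influence region must span a cell)
  r0 <- if (is.null(wires)) 2e-5 else
    max(2 * wires$wire_radius, stats::median(mesh$h))
  rx <- config$reaction %||% list()
  rx$r0 <- rx$r0 %||% r0
  reaction <- do.call(reaction_params, rx)

  inlet_cfg <- config$inlet %||% list()
  Fg <- if (!is.null(inlet_cfg$Fg_mg_dl))
    fibrinogen_mg_dl_to_uM(inlet_cfg$Fg_mg_dl) else (inlet_cfg$Fg %||% 7.0)
  inlet <- inlet_concentrations(PT = inlet_cfg$PT %||% 1.4,
                                AT = inlet_cfg$AT %||% 2.41, Fg = Fg)

  fl <- config$flow
  bc <- flow_bc(type = fl$type %||% "velocity",
                mean_velocity = fl$mean_velocity, flow_rate = fl$flow_rate,
                dp = fl$dp)

  params <- model_params(
    reaction = reaction,
    fluid = do.call(fluid_properties, config$fluid %||% list()),
    porosity = do.call(porosity_params, config$porosity %||% list()),
    D = species_diffusivities(config$diffusivity %||% 5e-11),
    inlet = inlet, bc = bc)

  cp <- config$coupling %||% list()
  tp <- config$transport %||% list()
  cfg <- coupling_config(
    eps1 = cp$eps1 %||% 1e-4, eps2 = cp$eps2 %||% 1e-3,
    max_coupled_steps = cp$max_coupled_steps %||% 500L,
    total_time_target = end_time %||% cp$total_time_target %||% 1.0,
    transport_time_cap = cp$transport_time_cap %||% Inf,
    transport = transport_config(
      courant = tp$courant %||% 0.5,
      scheme = tp$scheme %||% "upwind1",
      rk_stages = tp$rk_stages %||% 2L,
      # the fibre-length averaging lets bounded fibrin seed neighbouring
      # cells (without it device occlusion cannot develop); at coarse
      # resolution the radius must span at least the local cell size
      fiber_length = max(tp$fiber_length %||% 4e-5,
                         2 * stats::median(mesh$h)),
      dt_cap = tp$dt_cap %||% Inf,
      wire_shear_delta = tp$wire_shear_delta %||% 1e-4))

  list(mesh = mesh, wires = wires, ib = ib, params = params, cfg = cfg,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
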