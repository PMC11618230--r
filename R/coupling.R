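# Quasi-steady staggered coupling: the steady flow (with the current Darcy
# clot force) is frozen while the transport-reaction system advances; the
# flow is re-solved only when the accumulated change in the porosity force
# would let the flow residual grow past the budget eps2.

#' Coupling configuration
#'
#' @param eps1 flow convergence tolerance (velocity change, m/s); default 1e-4
#' @param eps2 allowed flow-residual growth before a re-solve (m/s); default
#'   1e-3; must exceed eps1
#' @param max_coupled_steps cap on coupled steps
#' @param total_time_target total simulated (global) transport time (s)
#' @param transport_time_cap longest transport phase without a re-solve (s)
#' @param checkpoint_dir directory for checkpoint files (NULL = none)
#' @param checkpoint_every write a checkpoint every this many coupled steps
#' @param flow flow solver config ([flow_config]); its eps1 is overridden
#' @param transport transport config ([transport_config])
#' @param store_trigger_series keep the per-transport-step residual-growth
#'   series (used by diagnostics/tests)
#' @return list of class `coupling_config`
#' @export
coupling_config <- function(eps1 = 1e-4, eps2 = 1e-3, max_coupled_steps = 50L,
                            total_time_target = 1.0,
                            transport_time_cap = Inf,
                            checkpoint_dir = NULL, checkpoint_every = 1L,
                            flow = flow_config(), transport = transport_config(),
                            store_trigger_series = TRUE) {
  if (!(eps2 > eps1 && eps1 > 0)) stop("need eps2 > eps1 > 0")
  flow$eps1 <- eps1
  structure(list(eps1 = eps1, eps2 = eps2,
                 max_coupled_steps = as.integer(max_coupled_steps),
                 total_time_target = total_time_target,
                 transport_time_cap = transport_time_cap,
                 checkpoint_dir = checkpoint_dir,
                 checkpoint_every = as.integer(checkpoint_every),
                 flow = flow, transport = transport,
                 store_trigger_series = store_trigger_series),
            class = "coupling_config")
}

#' Re-solve trigger of the staggered coupling
#'
#' Estimates the growth of the flow residual caused by the change of the
#' Darcy force since the last flow solution,
#' deltaF = max_k |pi/rho (phi(Cfb_now) - phi(Cfb_ref)) u_k|, and reports
#' whether dt * deltaF has reached the budget eps2.
#'
#' @param Cfb_now,Cfb_ref per-element bounded fibrin now and at the last
#'   flow solve (uM)
#' @param u_elem per-element velocity magnitude (m/s)
#' @param pp [porosity_params]
#' @param fp [fluid_properties]
#' @param dt current transport timestep (s)
#' @param eps2 residual budget (m/s)
#' @return list(trigger = logical, deltaR = dt * deltaF)
#' @export
resolve_trigger <- function(Cfb_now, Cfb_ref, u_elem, pp, fp, dt, eps2) {
  dphi <- hill(Cfb_now / pp$Cfb0, pp$n_hill) - hill(Cfb_ref / pp$Cfb0, pp$n_hill)
  deltaF <- max(abs(dphi) * pp$pi_coeff / fp$rho * u_elem)
  deltaR <- dt * deltaF
  list(trigger = deltaR >= eps2, deltaR = deltaR)
}

#' Bundle of physical parameters for a coupled run
#'
#' @param reaction [reaction_params]
#' @param fluid [fluid_properties]
#' @param porosity [porosity_params]
#' @param D [species_diffusivities]
#' @param inlet named 6-vector of inlet concentrations (uM)
#' @param bc [flow_bc]
#' @return list of class `model_params`
#' @export
model_params <- function(reaction = reaction_params(),
                         fluid = fluid_properties(),
                         porosity = porosity_params(),
                         D = species_diffusivities(),
                         inlet = inlet_concentrations(),
                         bc = flow_bc(mean_velocity = 0.015)) {
  structure(list(reaction = reaction, fluid = fluid, porosity = porosity,
                 D = D, inlet = inlet, bc = bc), class = "model_params")
}

#' Run the coupled flow / transport-reaction simulation
#'
#' Starting from zero concentrations and a converged clot-free flow, the
#' transport equations advance on the frozen (u, tau) field until the
#' [resolve_trigger] fires (or a phase time cap is hit), at which point the
#' porosity field is updated and the flow re-solved (warm-started) to eps1,
#' the shear recomputed and transport resumed. Stops at the global-time
#' target or the coupled-step cap.
#'
#' @param mesh a `tet_mesh`
#' @param ib an `immersed_boundary`
#' @param params [model_params]
#' @param cfg [coupling_config]
#' @param wires optional `wire_set` (only used for coverage metrics)
#' @param restart path to a checkpoint file to resume from
#' @param progress print a line per coupled step
#' @param on_step optional callback `function(step, time, C, flow)` invoked
#'   after every coupled step (used e.g. to write per-step field files)
#' @return object of class `run_state`: final `C` (ne x 6), `flow`,
#'   `global_time`, `coupled_step`, `metrics` (data.frame, one row per
#'   coupled step), `trigger_series` (data.frame of per-step dt and deltaR
#'   with re-solve flags), `resolve_residuals` (flow residual immediately
#'   after each re-solve), `n_flow_solves`, `clipped`
#' @export
run_coupled <- function(mesh, ib, params, cfg = coupling_config(),
                        wires = NULL, restart = NULL, progress = FALSE,
                        on_step = NULL) {
  fops <- flow_operators(mesh)
  tops <- transport_operators(mesh, ib, cfg$transport)
  ne <- nrow(mesh$tets)
  p <- params$reaction; fp <- params$fluid; pp <- params$porosity

  if (!is.null(restart)) {
    st <- readRDS(restart)
    C <- st$C; flow <- st$flow; Cfb_ref <- st$Cfb_ref
    global_time <- st$global_time; step_idx <- st$coupled_step
    metrics_rows <- st$metrics_rows; trig_dt <- st$trig_dt
    trig_dR <- st$trig_dR; trig_resolve <- st$trig_resolve
    resolve_residuals <- st$resolve_residuals
    n_solves <- st$n_flow_solves; clipped <- st$clipped
  } else {
    C <- matrix(0, ne, 6L, dimnames = list(NULL, SPECIES))
    flow <- solve_steady(mesh, ib, Cfb = 0, bc = params$bc, fp = fp, pp = pp,
                         cfg = cfg$flow, ops = fops)
    Cfb_ref <- C[, 6L]
    global_time <- 0; step_idx <- 0L
    metrics_rows <- list()
    trig_dt <- numeric(0); trig_dR <- numeric(0); trig_resolve <- logical(0)
    resolve_residuals <- utils::tail(flow$residual_history, 1)
    n_solves <- 1L; clipped <- 0
    first_crossing <- NULL
  }
  if (is.null(restart)) Wavg <- tops$W else {
    Wavg <- tops$W; first_crossing <- st$first_crossing
  }
  attach_flow <- function(tops, flow) {
    spd <- sqrt(rowSums(flow$u^2))
    t4 <- mesh$tets
    spd_e <- (spd[t4[, 1]] + spd[t4[, 2]] + spd[t4[, 3]] + spd[t4[, 4]]) / 4
    tau_eff <- wire_scale_shear(flow$tau_elem, spd_e, ib$r_field, p$r0,
                                fp$mu, cfg$transport$wire_shear_delta)
    transport_set_flow(tops, u = flow$u, tau_elem = tau_eff, p = p)
  }
  tops <- attach_flow(tops, flow)
  loc <- if (!is.null(mesh$geom$neck_plane)) build_locator(mesh) else NULL
  sac_sel <- if (!is.null(mesh$geom$sac_center)) {
    sqrt(rowSums(sweep(mesh$centroid, 2, mesh$geom$sac_center)^2)) <=
      mesh$geom$sac_radius & mesh$centroid[, 2] > mesh$geom$vessel_d / 2
  } else NULL
  sac_speed <- function(flow) {
    if (is.null(sac_sel) || !any(sac_sel)) return(NA_real_)
    spd <- sqrt(rowSums(flow$u^2))
    t4 <- mesh$tets
    spd_e <- (spd[t4[, 1]] + spd[t4[, 2]] + spd[t4[, 3]] + spd[t4[, 4]]) / 4
    stats::weighted.mean(spd_e[sac_sel], mesh$V[sac_sel])
  }

  while (step_idx < cfg$max_coupled_steps &&
         global_time < cfg$total_time_target - 1e-15) {
    step_idx <- step_idx + 1L
    t_phase <- 0
    triggered <- FALSE
    while (TRUE) {
      cavg <- as.numeric(Wavg %*% C[, 6L])
      if (is.null(first_crossing) && any(cavg > pp$Cfb0)) {
        first_crossing <- list(elem = which.max(cavg), time = global_time)
      }
      dt <- stable_dt(tops, C, params$D, p, cfg$transport, Cfb_avg = cavg)
      dt <- min(dt, cfg$total_time_target - global_time,
                cfg$transport_time_cap - t_phase)
      stp <- transport_step(tops, C, params$D, p, params$inlet, dt,
                            cfg$transport, Cfb_avg1 = cavg)
      C <- stp$C; clipped <- clipped + stp$clipped
      global_time <- global_time + dt
      t_phase <- t_phase + dt
      tr <- resolve_trigger(C[, 6L], Cfb_ref, tops$u_elem, pp, fp, dt, cfg$eps2)
      if (cfg$store_trigger_series) {
        trig_dt <- c(trig_dt, dt); trig_dR <- c(trig_dR, tr$deltaR)
        trig_resolve <- c(trig_resolve, tr$trigger)
      }
      if (tr$trigger) { triggered <- TRUE; break }
      if (t_phase >= cfg$transport_time_cap - 1e-15 ||
          global_time >= cfg$total_time_target - 1e-15) break
    }

    if (triggered) {
      flow <- solve_steady(mesh, ib, Cfb = C[, 6L], bc = params$bc, fp = fp,
                           pp = pp, cfg = cfg$flow, ops = fops,
                           init = list(u = flow$u, p = flow$p))
      if (!flow$converged)
        stop("coupled run aborted: flow re-solve did not converge at step ",
             step_idx)
      resolve_residuals <- c(resolve_residuals,
                             utils::tail(flow$residual_history, 1))
      n_solves <- n_solves + 1L
      Cfb_ref <- C[, 6L]
      tops <- attach_flow(tops, flow)
    }

    metrics_rows[[step_idx]] <- data.frame(
      step = step_idx, time = global_time, resolved = triggered,
      total_Fb = sum(C[, 6L] * mesh$V), total_Fn = sum(C[, 5L] * mesh$V),
      max_Fb = max(C[, 6L]),
      pressure_drop = .pressure_drop(mesh, flow),
      inflow = if (!is.null(loc))
        aneurysm_inflow(mesh, flow$u, loc = loc) else NA_real_,
      sac_speed = sac_speed(flow),
      neck_crossed = !is.null(first_crossing))
    if (progress)
      message(sprintf("step %3d t=%.4fs resolve=%s totFb=%.3e maxFb=%.3f",
                      step_idx, global_time, triggered,
                      metrics_rows[[step_idx]]$total_Fb, max(C[, 6L])))

    if (!is.null(on_step)) on_step(step_idx, global_time, C, flow)

    if (!is.null(cfg$checkpoint_dir) &&
        step_idx %% cfg$checkpoint_every == 0L) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(C = C, flow = flow, Cfb_ref = Cfb_ref,
                   global_time = global_time, coupled_step = step_idx,
                   metrics_rows = metrics_rows, trig_dt = trig_dt,
                   trig_dR = trig_dR, trig_resolve = trig_resolve,
                   resolve_residuals = resolve_residuals,
                   n_flow_solves = n_solves, clipped = clipped,
                   first_crossing = first_crossing),
              file.path(cfg$checkpoint_dir,
                        sprintf("step_%04d.rds", step_idx)))
    }
  }

  out <- list(C = C, flow = flow, global_time = global_time,
              coupled_step = step_idx,
              metrics = do.call(rbind, metrics_rows),
              trigger_series = data.frame(dt = trig_dt, deltaR = trig_dR,
                                          resolved = trig_resolve),
              resolve_residuals = resolve_residuals,
              n_flow_solves = n_solves, clipped = clipped,
              Cfb_ref = Cfb_ref, first_crossing = first_crossing)
  class(out) <- "run_state"
  out
}

#' @export
print.run_state <- function(x, ...) {
  cat("run_state:", x$coupled_step, "coupled steps, global time",
      format(x$global_time, digits = 5), "s,", x$n_flow_solves, "flow solves\n")
  cat("  total bounded fibrin:",
      format(sum(utils::tail(x$metrics$total_Fb, 1)), digits = 5), "uM m^3\n")
  invisible(x)
}

.pressure_drop <- function(mesh, flow) {
  mean(flow$p[mesh$node_tag == 1L]) - mean(flow$p[mesh$node_tag == 2L])
}

#' Volumetric inflow rate through a plane disc
#'
#' Integrates max(u . n, 0) over the disc by polar quadrature with nodal
#' velocity interpolation; sample points outside the mesh contribute zero
#' (they lie in wall/wire territory).
#'
#' @param mesh a `tet_mesh`; the sidewall geometry's stored neck plane is
#'   used when `plane` is NULL
#' @param u nodal velocity
#' @param plane list(center, normal, radius)
#' @param nr,ntheta quadrature resolution
#' @param loc optional cached locator
#' @return inflow rate (m^3/s)
#' @export
aneurysm_inflow <- function(mesh, u, plane = NULL, nr = 10L, ntheta = 24L,
                            loc = NULL) {
  if (is.null(plane)) plane <- mesh$geom$neck_plane
  if (is.null(plane)) stop("no plane given and none stored in the mesh")
  if (is.null(loc)) loc <- build_locator(mesh)
  n <- plane$normal / sqrt(sum(plane$normal^2))
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  R <- plane$radius
  redge <- seq(0, R, length.out = nr + 1L)
  rmid <- (redge[-1] + redge[-(nr + 1L)]) / 2
  warea <- pi * diff(redge^2) / ntheta
  th <- (seq_len(ntheta) - 0.5) * 2 * pi / ntheta
  pts <- matrix(0, nr * ntheta, 3L)
  w <- numeric(nr * ntheta)
  q <- 0L
  for (i in seq_len(nr)) for (j in seq_len(ntheta)) {
    q <- q + 1L
    pts[q, ] <- plane$center + rmid[i] * (cos(th[j]) * e1 + sin(th[j]) * e2)
    w[q] <- warea[i]
  }
  lc <- locate_points(loc, pts)
  uv <- interp_nodal(loc, lc, u)
  un <- uv %*% n
  un[is.na(un)] <- 0
  sum(w * pmax(un, 0))
}

#' Fraction of the device pore surface covered by bounded fibrin
#'
#' Samples the deployment surface between the wires and reports the fraction
#' of sample points whose containing element has a neighbourhood-averaged
#' bounded fibrin above the porosity threshold Cfb0.
#'
#' @param mesh a `tet_mesh`
#' @param C species matrix (ne x 6)
#' @param wires a `wire_set`
#' @param pp [porosity_params]
#' @param W optional neighbourhood averaging matrix
#' @param n_samples sampling density
#' @param loc optional cached locator
#' @return covered fraction in [0, 1]
#' @export
covered_cell_fraction <- function(mesh, C, wires, pp, W = NULL,
                                  n_samples = 400L, loc = NULL) {
  if (is.null(loc)) loc <- build_locator(mesh)
  if (is.null(W)) W <- neighbor_average_matrix(mesh, 4e-5)
  Cavg <- as.numeric(W %*% C[, 6L])
  if (wires$type == "screen") {
    R <- wires$surface_radius
    m <- ceiling(sqrt(n_samples))
    g <- as.matrix(expand.grid(y = seq(-R, R, length.out = m),
                               z = seq(-R, R, length.out = m)))
    g <- g[g[, 1]^2 + g[, 2]^2 < (0.95 * R)^2, , drop = FALSE]
    pts <- cbind(wires$center_s, g)
  } else {
    ns <- ceiling(sqrt(n_samples)); np <- ns
    sv <- seq(wires$center_s - wires$length / 2,
              wires$center_s + wires$length / 2, length.out = ns)
    psiv <- seq(0, 2 * pi, length.out = np + 1L)[-1]
    g <- expand.grid(s = sv, psi = psiv)
    pts <- .on_surface(g$s, g$psi, wires$surface_radius, wires$curvature_radius)
  }
  lc <- locate_points(loc, pts)
  ok <- !is.na(lc$elem)
  if (!any(ok)) return(0)
  mean(Cavg[lc$elem[ok]] > pp$Cfb0)
}

#' Summary metrics of a run state
#'
#' @param state a `run_state`
#' @param mesh the mesh it was run on
#' @param wires optional `wire_set` for coverage
#' @param pp [porosity_params] (for the coverage threshold)
#' @param plane optional plane for inflow (defaults to the stored neck plane)
#' @return named list: total bounded fibrin (uM m^3), pressure drop (Pa),
#'   inflow rate (m^3/s or NA), covered fraction (or NA)
#' @export
run_metrics <- function(state, mesh, wires = NULL, pp = porosity_params(),
                        plane = NULL) {
  loc <- build_locator(mesh)
  inflow <- if (!is.null(plane) || !is.null(mesh$geom$neck_plane))
    aneurysm_inflow(mesh, state$flow$u, plane, loc = loc) else NA_real_
  covered <- if (!is.null(wires))
    covered_cell_fraction(mesh, state$C, wires, pp, loc = loc) else NA_real_
  list(total_bounded_fibrin = sum(state$C[, 6L] * mesh$V),
       pressure_drop = .pressure_drop(mesh, state$flow),
       inflow_rate = inflow, covered_fraction = covered)
}
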