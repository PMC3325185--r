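#' 3D reaction-diffusion simulation of invadopodial ECM degradation
#'
#' The extracellular space is discretized into a regular voxel grid. Membrane
#' species live on an invadopodium patch on one boundary face (their diffusion
#' is zero; FRAP shows lateral mobility is negligible); TIMP-2 and the MMP-2
#' species diffuse; the fibronectin-like ECM substrate and every ECM-bound
#' complex are immobile. Diffusion uses explicit central differences with
#' no-flux boundaries on all faces (closed chamber, so the TIMP-2/proMMP-2
#' monomer ledgers are conserved), applied inside each stage of the same
#' fixed-step RK4 scheme as the well-mixed model. The explicit-stability
#' bound `dt < voxel^2 / (6 * max D)` is enforced.
#'
#' Voxel-level parameters equal the well-mixed ones, so a grid in which every
#' voxel carries membrane and ECM, with all diffusion switched off, reproduces
#' the well-mixed trajectories voxel by voxel - the module's primary
#' correctness oracle.
#'
#' @name spatial-sim
NULL

#' Build a spatial grid
#'
#' @param nx,ny,nz Grid dimensions (voxels).
#' @param voxel_um Voxel edge length (um).
#' @param membrane Either `"patch"` (a centred patch on the z = 1 face whose
#'   edge is about half the face) or `"all"` (every voxel carries membrane;
#'   with zero diffusion this collapses to the well-mixed model), or a logical
#'   vector of length `nx*ny*nz`.
#' @param ecm `"layer"` (the ECM fills the z = 1 voxel layer adjacent to the
#'   membrane face) or `"all"`, or a logical vector.
#' @param diffusion_um2_s Named diffusion coefficients (um^2/s) for the
#'   soluble species; everything not named is immobile.
#' @export
build_grid <- function(nx = 4, ny = 4, nz = 4, voxel_um = 1,
                       membrane = "patch", ecm = "layer",
                       diffusion_um2_s = c(T2 = 10, M2pro = 10, M2act = 10,
                                           "M2act.T2" = 10)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, voxel_um > 0, all(diffusion_um2_s >= 0))
  V <- nx * ny * nz
  vox <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  pick_face <- function(kind) {
    if (is.logical(kind)) {
      stopifnot(length(kind) == V)
      return(kind)
    }
    if (kind == "all") return(rep(TRUE, V))
    if (kind == "layer") return(vox$iz == 1L)
    # centred patch on the z = 1 face
    hx <- max(1L, round(nx / 2)); hy <- max(1L, round(ny / 2))
    x0 <- floor((nx - hx) / 2); y0 <- floor((ny - hy) / 2)
    vox$iz == 1L & vox$ix > x0 & vox$ix <= x0 + hx &
      vox$iy > y0 & vox$iy <= y0 + hy
  }
  membrane_mask <- pick_face(if (identical(membrane, "patch")) "patch" else membrane)
  ecm_mask <- pick_face(if (identical(ecm, "layer")) "layer" else ecm)
  if (!any(membrane_mask)) stop("membrane mask is empty")
  if (identical(membrane, "patch") && any(membrane_mask & vox$iz != 1L))
    stop("membrane patch must lie on one boundary face")
  structure(list(nx = nx, ny = ny, nz = nz, voxel_um = voxel_um,
                 membrane_mask = membrane_mask, ecm_mask = ecm_mask,
                 diffusion = diffusion_um2_s),
            class = "spatial_grid")
}

#' Largest stable explicit-diffusion step for a grid
#' @param grid A `spatial_grid`.
#' @export
max_stable_dt <- function(grid) {
  dmax <- if (length(grid$diffusion)) max(grid$diffusion) else 0
  if (dmax == 0) Inf else grid$voxel_um^2 / (6 * dmax)
}

#' Run the spatiotemporal model
#'
#' @param grid A `spatial_grid`.
#' @param scenario A `sim_scenario`; per-voxel parameters equal the well-mixed
#'   ones. Soluble species start uniform over all voxels, ECM in the ECM
#'   layer, membrane species (at the turnover-only steady state) and the
#'   vesicular reservoir in the membrane patch.
#' @param t_end End time (s).
#' @param dt Step (s); defaults to 80% of the explicit-diffusion stability
#'   bound, capped at 0.02 s. Steps violating the bound are rejected with the
#'   maximal admissible value.
#' @param out_dt Output sampling of the volume totals (s).
#' @param snapshot_times Times (s) at which full species-by-voxel fields are
#'   kept.
#' @return A `spatial_result`: `times`, voxel-mean concentrations,
#'   `ecm_remaining` (volume-integrated intact fraction), snapshots, final
#'   field, and the grid.
#' @export
run_spatial <- function(grid, scenario, t_end = 800, dt = NULL, out_dt = 1,
                        snapshot_times = numeric(0)) {
  stopifnot(inherits(grid, "spatial_grid"), inherits(scenario, "sim_scenario"))
  bound <- max_stable_dt(grid)
  if (is.null(dt)) {
    dt <- min(0.02, 0.8 * bound)
    dt <- out_dt / ceiling(out_dt / dt)  # samples land exactly on the output grid
  }
  if (dt >= bound)
    stop(sprintf("dt = %g violates the diffusion stability bound; need dt < %g",
                 dt, bound))
  net <- scenario_network(scenario)
  sp <- net$species
  S <- nrow(sp); V <- grid$nx * grid$ny * grid$nz
  y0 <- matrix(0, S, V)
  rownames(y0) <- sp$id
  set_uniform <- function(id, value, mask) {
    if (id %in% sp$id) y0[id, mask] <<- value
  }
  surf <- scenario$surface_state
  if (is.null(surf)) surf <- steady_surface_state(scenario$rates)
  for (nm in names(surf)) set_uniform(nm, surf[[nm]], grid$membrane_mask)
  set_uniform("M14_ves", scenario$ves_uM, grid$membrane_mask)
  set_uniform("T2", scenario$timp2_nM / 1000, rep(TRUE, V))
  set_uniform("M2pro", scenario$m2pro_uM, rep(TRUE, V))
  set_uniform("fn", scenario$fn_uM, grid$ecm_mask)

  dcoef <- numeric(S)
  names(dcoef) <- sp$id
  known <- intersect(names(grid$diffusion), sp$id)
  dcoef[known] <- grid$diffusion[known]
  # membrane, internalized, reservoir and ECM-anchored species never diffuse
  immobile <- sp$type %in% c("membrane", "internalized", "reservoir") |
    sp$compartment == "ecm"
  dcoef[immobile] <- 0

  comp <- compile_network(net)
  # immobile species exist only where they were seeded, so their reactions can
  # be restricted to those voxels (membrane patch / ECM layer)
  sp_type <- stats::setNames(sp$type, sp$id)
  sp_comp <- stats::setNames(sp$compartment, sp$id)
  rmask <- vapply(seq_len(nrow(net$reactions)), function(i) {
    lhs <- split_side(net$reactions$reactants[i])
    if (any(sp_type[lhs] %in% c("membrane", "internalized", "reservoir"))) 1L
    else if (any(sp_comp[lhs] == "ecm")) 2L
    else 0L
  }, integer(1))
  out_every <- max(1L, as.integer(round(out_dt / dt)))
  raw <- spatial_integrate_cpp(comp, y0, c(grid$nx, grid$ny, grid$nz),
                               as.numeric(dcoef),
                               as.integer(grid$membrane_mask),
                               as.integer(grid$ecm_mask), rmask,
                               grid$voxel_um, dt, t_end, out_every,
                               snapshot_times)
  conc <- raw$mean_conc
  colnames(conc) <- sp$id
  wi <- intact_fn_weights(net)
  intact <- as.numeric(conc %*% wi)
  structure(list(times = raw$times, conc = conc, network = net,
                 fn0 = intact[1],
                 ecm_remaining = if (intact[1] > 0) intact / intact[1] else
                   rep(NA_real_, length(raw$times)),
                 snapshots = raw$snapshots, snapshot_times = snapshot_times,
                 final_field = raw$final_field, grid = grid, dt = dt),
            class = c("spatial_result", "sim_result"))
}

#' Half-degradation time of the volume-integrated ECM
#'
#' Same contract as [tau_half()], applied to the global (volume-summed)
#' intact-ECM fraction of a spatial run.
#'
#' @param result A `spatial_result`.
#' @param level Crossing level.
#' @export
spatial_tau_half <- function(result, level = 0.5) tau_half(result, level)

#' Freeze the turnover of a scenario after surface equilibration
#'
#' Returns a scenario whose turnover rates are all zero but whose surface
#' pools start from the control steady state, i.e. insertion and
#' internalization are switched off after equilibration. Used for the
#' no-turnover comparison in which ECM degradation stalls.
#'
#' @param scenario A `sim_scenario`.
#' @export
disable_turnover <- function(scenario) {
  if (is.null(scenario$surface_state))
    scenario <- pre_equilibrate(scenario)
  for (nm in c("k_D", "k_Xint", "C_D", "k_Xins"))
    scenario$rates[[nm]] <- 0
  scenario
}
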