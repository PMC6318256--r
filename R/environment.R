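#' Compartment specification
#'
#' One box of the model environment: a water layer or a bottom-sediment
#' slab. Geometry may be given either as an explicit `volume` or through the
#' trapezoidal-basin fields (`length`, surface/floor widths and depth bounds),
#' from which [layer_volume()] derives the volume.
#'
#' @param id Compartment identifier (e.g. `"NL3"`, `"ST"`).
#' @param medium `"surface_water"` or `"bottom_sediment"`.
#' @param depth_top,depth_bottom Depth bounds of the layer, m.
#' @param length Horizontal length, m.
#' @param width_surface,width_floor Basin width at 0 m and at `floor_depth`, m.
#' @param floor_depth Depth at which the basin reaches `width_floor`, m.
#' @param volume Explicit volume override, m3.
#' @param temperature Degrees C.
#' @param ph Ambient pH.
#' @param oc_fraction Organic-carbon mass fraction of the solids (sediment
#'   solids, or suspended solids via `ss_oc_fraction` for water).
#' @param porosity Sediment water-volume fraction.
#' @param ss_volume_fraction Suspended-solids volume fraction of a water
#'   compartment.
#' @param ss_oc_fraction Organic-carbon fraction of suspended solids.
#' @param photolysis_multiplier Depth-band photolysis factor; derived from the
#'   depth bounds when `NULL` (water) and fixed at 0 for sediments.
#' @return A one-row `data.frame`.
#' @export
compartment_spec <- function(id, medium = c("surface_water", "bottom_sediment"),
                             depth_top = NA, depth_bottom = NA,
                             length = NA, width_surface = NA, width_floor = NA,
                             floor_depth = NA, volume = NULL,
                             temperature = 15, ph = 7,
                             oc_fraction = 0.06, porosity = 0.8,
                             ss_volume_fraction = 0, ss_oc_fraction = 0.25,
                             photolysis_multiplier = NULL) {
  medium <- match.arg(medium)
  if (is.null(volume)) {
    volume <- layer_volume(depth_top, depth_bottom, length,
                           width_surface, width_floor, floor_depth)
  }
  if (!is.finite(volume) || volume <= 0) stop("volume must be > 0 for ", id)
  if (oc_fraction < 0 || oc_fraction > 1) stop("oc_fraction outside [0,1]")
  if (porosity < 0 || porosity > 1) stop("porosity outside [0,1]")
  if (is.null(photolysis_multiplier)) {
    photolysis_multiplier <- if (medium == "surface_water" &&
                                 is.finite(depth_top) && is.finite(depth_bottom))
      photolysis_depth_multiplier(depth_top, depth_bottom) else 0
  }
  if (medium == "bottom_sediment" && photolysis_multiplier != 0)
    stop("sediment compartments have no photolysis (", id, ")")
  data.frame(id = id, medium = medium,
             depth_top = depth_top, depth_bottom = depth_bottom,
             volume = volume, temperature = temperature, ph = ph,
             oc_fraction = oc_fraction, porosity = porosity,
             ss_volume_fraction = ss_volume_fraction,
             ss_oc_fraction = ss_oc_fraction,
             photolysis_multiplier = photolysis_multiplier,
             stringsAsFactors = FALSE)
}

#' Trapezoidal water-layer volume
#'
#' Basin width is interpolated linearly from `width_surface` at 0 m to
#' `width_floor` at `floor_depth`; the layer volume is length times mean width
#' across the layer times its thickness.
#'
#' @param depth_top,depth_bottom Layer bounds, m (`top < bottom`).
#' @param length Horizontal length, m.
#' @param width_surface,width_floor Widths at 0 m and `floor_depth`, m.
#' @param floor_depth Depth of the basin floor, m.
#' @return Volume, m3.
#' @export
layer_volume <- function(depth_top, depth_bottom, length,
                         width_surface, width_floor, floor_depth) {
  if (!is.finite(depth_top) || !is.finite(depth_bottom) ||
      depth_bottom <= depth_top)
    stop("degenerate layer: need depth_top < depth_bottom")
  w <- function(d) width_surface + (width_floor - width_surface) * d / floor_depth
  length * mean(c(w(depth_top), w(depth_bottom))) * (depth_bottom - depth_top)
}

#' Flow link between compartments
#'
#' Advection (one-way volumetric flow; `source`/`target` may be the boundary
#' names `"inflow"`/`"outflow"`), mixing (symmetric volumetric exchange), or
#' sediment exchange (diffusive mass-transfer plus solids deposition,
#' resuspension and burial over an interface area).
#'
#' @param kind `"advection"`, `"mixing"` or `"sediment_exchange"`.
#' @param source,target Compartment ids (or boundary names for advection).
#' @param rate Volumetric rate, m3/h (advection/mixing).
#' @param area Interface area, m2 (sediment exchange).
#' @param mtc_diff Diffusive mass-transfer coefficient, m/h.
#' @param u_dep,u_res,u_bur Deposition, resuspension and burial solids
#'   velocities, m/h.
#' @return One-row `data.frame`.
#' @export
flow_link <- function(kind = c("advection", "mixing", "sediment_exchange"),
                      source, target, rate = NA,
                      area = NA, mtc_diff = 4e-4,
                      u_dep = 1e-6, u_res = 4e-7, u_bur = 2e-7) {
  kind <- match.arg(kind)
  if (kind %in% c("advection", "mixing")) {
    if (!is.finite(rate) || rate < 0) stop("rate must be >= 0 (", source,
                                           " -> ", target, ")")
  } else {
    if (!is.finite(area) || area <= 0) stop("sediment_exchange needs area > 0")
    if (any(c(mtc_diff, u_dep, u_res, u_bur) < 0))
      stop("sediment-exchange parameters must be >= 0")
  }
  data.frame(kind = kind, source = source, target = target, rate = rate,
             area = area, mtc_diff = mtc_diff, u_dep = u_dep, u_res = u_res,
             u_bur = u_bur, stringsAsFactors = FALSE)
}

#' Emission into a compartment
#'
#' A continuous input, given either as an effluent water flow carrying a
#' concentration, or as a direct molar rate.
#'
#' @param compartment Target compartment id.
#' @param chemical Chemical id.
#' @param water_flow Effluent water flow, m3/h (0 for direct molar input).
#' @param concentration Effluent concentration, g/m3.
#' @param mol_h Direct molar input rate, mol/h (used when no concentration is
#'   given).
#' @param molecular_weight g/mol; required to convert a concentration input.
#' @return One-row `data.frame` with the resolved molar rate.
#' @export
emission_spec <- function(compartment, chemical, water_flow = 0,
                          concentration = NA, mol_h = NA,
                          molecular_weight = NA) {
  if (is.finite(concentration)) {
    if (!is.finite(molecular_weight))
      stop("molecular_weight needed to convert a concentration emission")
    mol_h <- water_flow * concentration / molecular_weight
  }
  if (!is.finite(mol_h) || mol_h < 0) stop("emission molar rate must be >= 0")
  data.frame(compartment = compartment, chemical = chemical,
             water_flow = water_flow, mol_h = mol_h, stringsAsFactors = FALSE)
}

#' Assemble and validate a model environment
#'
#' Binds compartments, flow links, emissions, chemical specs and the reaction
#' table into a validated scenario. Validation is exhaustive (all problems are
#' reported together): link endpoints must resolve, the water-compartment flow
#' graph must be connected, emission chemicals must exist, and every water
#' compartment must satisfy hydraulic continuity (advective inflow including
#' emission water equals advective outflow, to 1e-9 relative).
#'
#' @param compartments `data.frame` of stacked [compartment_spec()] rows.
#' @param links `data.frame` of stacked [flow_link()] rows.
#' @param emissions `data.frame` of stacked [emission_spec()] rows.
#' @param chemicals Named list of [chemical_spec()] objects.
#' @param reactions A [reaction_table()].
#' @param options List of engine options; see Details. Defaults:
#'   `gamma = log(2)/10` (rate-halving per 10 C), `t_ref = 25` C,
#'   `z_water = 1` (nominal water fugacity capacity; all outputs are invariant
#'   to it), `solids_density = 2.4` kg/l.
#' @param validate_continuity Set `FALSE` to skip the hydraulic-continuity
#'   check (used for deliberately re-plumbed sensitivity variants).
#' @return Object of class `environment_spec`.
#' @export
environment_spec <- function(compartments, links, emissions, chemicals,
                             reactions, options = list(),
                             validate_continuity = TRUE) {
  defaults <- list(gamma = log(2) / 10, t_ref = 25, z_water = 1,
                   solids_density = 2.4)
  options <- utils::modifyList(defaults, options)
  env <- structure(list(compartments = compartments, links = links,
                        emissions = emissions, chemicals = chemicals,
                        reactions = reactions, options = options,
                        validate_continuity = validate_continuity),
                   class = "environment_spec")
  errs <- validate_environment(env)
  if (length(errs)) stop("invalid environment:\n  - ",
                         paste(errs, collapse = "\n  - "))
  env
}

# Exhaustive validation; returns a character vector of problems (empty = ok).
validate_environment <- function(env) {
  errs <- character()
  comp <- env$compartments
  if (anyDuplicated(comp$id))
    errs <- c(errs, "duplicate compartment ids")
  boundary <- c("inflow", "outflow")
  for (i in seq_len(nrow(env$links))) {
    l <- env$links[i, ]
    ok_src <- l$source %in% comp$id ||
      (l$kind == "advection" && l$source %in% boundary)
    ok_tgt <- l$target %in% comp$id ||
      (l$kind == "advection" && l$target %in% boundary)
    if (!ok_src) errs <- c(errs, paste0("link source not found: ", l$source))
    if (!ok_tgt) errs <- c(errs, paste0("link target not found: ", l$target))
  }
  for (i in seq_len(nrow(env$emissions))) {
    e <- env$emissions[i, ]
    if (!e$compartment %in% comp$id)
      errs <- c(errs, paste0("emission target not found: ", e$compartment))
    if (!e$chemical %in% names(env$chemicals))
      errs <- c(errs, paste0("emission chemical not found: ", e$chemical))
  }
  rchem <- unique(c(env$reactions$parent,
                    setdiff(env$reactions$product, "other")))
  miss <- setdiff(rchem, names(env$chemicals))
  if (length(miss))
    errs <- c(errs, paste0("reaction references unknown chemical: ",
                           paste(miss, collapse = ", ")))
  # hydraulic continuity per water compartment
  if (env$validate_continuity && nrow(env$links)) {
    adv <- env$links[env$links$kind == "advection", , drop = FALSE]
    for (id in comp$id[comp$medium == "surface_water"]) {
      if (!nrow(adv)) break
      inflow <- sum(adv$rate[adv$target == id]) +
        sum(env$emissions$water_flow[env$emissions$compartment == id])
      outflow <- sum(adv$rate[adv$source == id])
      if (inflow + outflow == 0) next
      if (abs(inflow - outflow) > 1e-9 * max(inflow, outflow))
        errs <- c(errs, sprintf(
          "hydraulic continuity violated in %s (in %.6g, out %.6g m3/h)",
          id, inflow, outflow))
    }
  }
  # connectivity of the water-compartment link graph
  wc <- comp$id[comp$medium == "surface_water"]
  if (length(wc) > 1 && nrow(env$links)) {
    adj <- env$links[env$links$source %in% wc & env$links$target %in% wc,
                     c("source", "target")]
    seen <- wc[1]; frontier <- wc[1]
    while (length(frontier)) {
      nb <- unique(c(adj$target[adj$source %in% frontier],
                     adj$source[adj$target %in% frontier]))
      frontier <- setdiff(nb, seen)
      seen <- c(seen, frontier)
    }
    if (length(setdiff(wc, seen)))
      errs <- c(errs, paste0("water compartments disconnected: ",
                             paste(setdiff(wc, seen), collapse = ", ")))
  }
  errs
}

#' @export
print.environment_spec <- function(x, ...) {
  nw <- sum(x$compartments$medium == "surface_water")
  ns <- sum(x$compartments$medium == "bottom_sediment")
  cat(sprintf("<environment_spec> %d water + %d sediment compartments, %d links\n",
              nw, ns, nrow(x$links)))
  cat(sprintf("  chemicals: %s\n", paste(names(x$chemicals), collapse = ", ")))
  cat(sprintf("  emissions: %d record(s); reactions: %d\n",
              nrow(x$emissions), nrow(x$reactions)))
  invisible(x)
}

#' Vertical mixing rate from turbulent diffusivity
#'
#' The diffusivity is divided by the vertical distance between the midpoints
#' of two adjacent layers to give a piston velocity, then multiplied by the
#' interface area.
#'
#' @param diffusivity cm2/s.
#' @param midpoint_distance m, > 0.
#' @param interface_area m2.
#' @return Volumetric exchange rate, m3/h.
#' @export
mixing_rate_from_diffusivity <- function(diffusivity, midpoint_distance,
                                         interface_area) {
  if (midpoint_distance <= 0) stop("midpoint_distance must be > 0")
  if (diffusivity < 0 || interface_area <= 0)
    stop("diffusivity must be >= 0 and interface_area > 0")
  (diffusivity * 1e-4 / midpoint_distance) * interface_area * 3600
}

#' Vertical mixing rate from a complete-mixing turnover time
#'
#' `G = volume / turnover_time`, applied as a symmetric exchange; by
#' convention the volume is the smaller of the two adjacent layers.
#'
#' @param volume m3.
#' @param turnover_time h (Inf = no mixing).
#' @return Volumetric exchange rate, m3/h.
#' @export
mixing_rate_from_turnover <- function(volume, turnover_time) {
  if (volume <= 0 || turnover_time <= 0)
    stop("volume and turnover_time must be > 0")
  volume / turnover_time
}
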