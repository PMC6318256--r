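# Packaged scenario builders: a two-area (N/S) stratified-lake effluent-plume
# environment and the downstream plug-flow transport segments.

# Width of a trapezoidal basin at depth d.
basin_width <- function(g, d) {
  g$width_surface + (g$width_floor - g$width_surface) * d / g$floor_depth
}

# Lake-bed strip area between two depths (both shores combined, projected).
bed_strip_area <- function(g, d1, d2) {
  g$length * (basin_width(g, d1) - basin_width(g, d2))
}

bed_floor_area <- function(g) g$length * g$width_floor

#' Default parameters of the packaged N-S lake scenario
#'
#' All tunables of [build_paijanne_ns()] with their defaults: layer depth
#' bounds (L1 0-0.1, L2 0.1-1, L3 1-5, L4 5-9, L5 9-15, L6 15-25 m), basin
#' geometry (300 m long areas; N 200->150 m wide over 0-15 m, S 300->200 m
#' over 0-25 m), western through-flow velocities (cm/s), printed
#' complete-mixing turnover times between adjacent layers (h), temperatures
#' (epilimnion/hypolimnion), suspended-solids and sediment properties,
#' sediment-exchange transfer parameters and the effluent emission.
#'
#' @return Named list of parameters.
#' @export
paijanne_defaults <- function() {
  list(
    depth_bounds = c(0, 0.1, 1, 5, 9, 15, 25),
    n_geometry = list(length = 300, width_surface = 200, width_floor = 150,
                      floor_depth = 15),
    s_geometry = list(length = 300, width_surface = 300, width_floor = 200,
                      floor_depth = 25),
    velocity_n = 1,        # cm/s, western inflow through the N area
    velocity_s_extra = 1,  # cm/s, additional western dilution inflow to S
    turnover_h = c(0.014, 22, 1600, 16000, 16000), # L1-L2 ... L5-L6
    epilimnion_temp = 15, hypolimnion_temp = 5, ph = 7,
    ss_volume_fraction = 3.6e-5, ss_oc_fraction = 0.25,
    sediment_oc = 0.06, sediment_thickness = 0.02, sediment_porosity = 0.8,
    mtc_diff = 4e-4, u_dep = 1e-6, u_res = 4e-7, u_bur = 2e-7,
    effluent_compartment = "NL3", effluent_flow = 1700, # m3/h
    effluent_conc_ug_l = c(IBU = 1, DCF = 1.5, CBZ = 0.05),
    gamma = log(2) / 10, t_ref = 25
  )
}

check_overrides <- function(defaults, overrides) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown override parameter(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

# Water-layer compartments of one lake area (prefix "NL"/"SL"/"TL").
area_layers <- function(prefix, g, n_layers, p) {
  db <- p$depth_bounds
  do.call(rbind, lapply(seq_len(n_layers), function(i) {
    compartment_spec(
      id = paste0(prefix, i), medium = "surface_water",
      depth_top = db[i], depth_bottom = db[i + 1],
      length = g$length, width_surface = g$width_surface,
      width_floor = g$width_floor, floor_depth = g$floor_depth,
      temperature = if (db[i] < 5) p$epilimnion_temp else p$hypolimnion_temp,
      ph = p$ph, ss_volume_fraction = p$ss_volume_fraction,
      ss_oc_fraction = p$ss_oc_fraction)
  }))
}

# cm/s -> m/h
cms_to_mh <- function(v) v * 36

# Advective cross-section of layer i (width at mid-depth x thickness).
layer_cross_section <- function(g, p, i) {
  db <- p$depth_bounds
  mid <- (db[i] + db[i + 1]) / 2
  basin_width(g, mid) * (db[i + 1] - db[i])
}

# Symmetric mixing links between vertically adjacent layers of one area.
area_mixing_links <- function(prefix, comps, n_layers, p, factor = 1) {
  do.call(rbind, lapply(seq_len(n_layers - 1), function(i) {
    a <- paste0(prefix, i); b <- paste0(prefix, i + 1)
    v <- min(comps$volume[comps$id == a], comps$volume[comps$id == b])
    flow_link("mixing", a, b,
              rate = factor * mixing_rate_from_turnover(v, p$turnover_h[i]))
  }))
}

sed_link <- function(p, water_id, sed_id, area) {
  flow_link("sediment_exchange", water_id, sed_id, area = area,
            mtc_diff = p$mtc_diff, u_dep = p$u_dep, u_res = p$u_res,
            u_bur = p$u_bur)
}

#' Build the packaged stratified-lake N-S effluent scenario
#'
#' Constructs the two-area (northern/southern) lake environment: water layers
#' NL1-NL5 and SL1-SL6 cut at the packaged depth bands, three 2-cm bottom
#' sediment slabs (ST under the 0-5 m bed, SM under 5-15 m, SB under the
#' deep southern 15-25 m bed), western through-flow advection in L1-L4
#' (N -> S -> outflow, plus an extra southern dilution inflow), symmetric
#' vertical mixing from the packaged turnover times, sediment exchange, and a
#' wastewater effluent emission into NL3 (1700 m3/h at 1/1.5/0.05 ug/l of
#' IBU/DCF/CBZ).
#'
#' @param overrides Named list overriding entries of [paijanne_defaults()];
#'   unknown names are rejected.
#' @param chemicals,reactions Chemical specs and reaction table; packaged
#'   tables by default.
#' @return A validated [environment_spec()].
#' @export
build_paijanne_ns <- function(overrides = list(),
                              chemicals = default_chemicals(),
                              reactions = default_reactions()) {
  p <- check_overrides(paijanne_defaults(), overrides)
  gN <- p$n_geometry; gS <- p$s_geometry
  db <- p$depth_bounds

  comps <- rbind(area_layers("NL", gN, 5, p), area_layers("SL", gS, 6, p))
  sed <- function(id, area) compartment_spec(
    id = id, medium = "bottom_sediment",
    volume = area * p$sediment_thickness,
    temperature = p$hypolimnion_temp, ph = p$ph,
    oc_fraction = p$sediment_oc, porosity = p$sediment_porosity)

  # bed areas in contact with each water layer
  a_ST_N <- bed_strip_area(gN, 0, 5);  a_ST_S <- bed_strip_area(gS, 0, 5)
  a_SM_NL4 <- bed_strip_area(gN, 5, 9)
  a_SM_NL5 <- bed_strip_area(gN, 9, 15) + bed_floor_area(gN)
  a_SM_SL4 <- bed_strip_area(gS, 5, 9); a_SM_SL5 <- bed_strip_area(gS, 9, 15)
  a_SB <- bed_strip_area(gS, 15, 25) + bed_floor_area(gS)
  comps <- rbind(comps,
                 sed("ST", a_ST_N + a_ST_S),
                 sed("SM", a_SM_NL4 + a_SM_NL5 + a_SM_SL4 + a_SM_SL5),
                 sed("SB", a_SB))

  vN <- cms_to_mh(p$velocity_n); vS <- cms_to_mh(p$velocity_s_extra)
  links <- list()
  for (i in 1:4) { # advection confined to L1-L4
    gn <- vN * layer_cross_section(gN, p, i)
    gs <- vS * layer_cross_section(gS, p, i)
    eff <- if (paste0("NL", i) == p$effluent_compartment) p$effluent_flow else 0
    links[[length(links) + 1]] <- flow_link("advection", "inflow",
                                            paste0("NL", i), rate = gn)
    links[[length(links) + 1]] <- flow_link("advection", paste0("NL", i),
                                            paste0("SL", i), rate = gn + eff)
    links[[length(links) + 1]] <- flow_link("advection", "inflow",
                                            paste0("SL", i), rate = gs)
    links[[length(links) + 1]] <- flow_link("advection", paste0("SL", i),
                                            "outflow", rate = gn + gs + eff)
  }
  links <- do.call(rbind, links)
  links <- rbind(links,
                 area_mixing_links("NL", comps, 5, p),
                 area_mixing_links("SL", comps, 6, p),
                 sed_link(p, "NL3", "ST", a_ST_N),
                 sed_link(p, "SL3", "ST", a_ST_S),
                 sed_link(p, "NL4", "SM", a_SM_NL4),
                 sed_link(p, "NL5", "SM", a_SM_NL5),
                 sed_link(p, "SL4", "SM", a_SM_SL4),
                 sed_link(p, "SL5", "SM", a_SM_SL5),
                 sed_link(p, "SL6", "SB", a_SB))

  conc <- p$effluent_conc_ug_l
  emis <- do.call(rbind, lapply(seq_along(conc), function(k) {
    chem <- names(conc)[k]
    emission_spec(p$effluent_compartment, chem,
                  # the water flow enters the hydraulic balance once
                  water_flow = if (k == 1L) p$effluent_flow else 0,
                  mol_h = p$effluent_flow * conc[[k]] * 1e-3 /
                    chemicals[[chem]]$molecular_weight)
  }))

  environment_spec(comps, links, emis, chemicals, reactions,
                   options = list(gamma = p$gamma, t_ref = p$t_ref,
                                  scenario = "paijanne_ns", params = p))
}

#' Default parameters of the transport segment environment
#'
#' @return Named list of parameters for [build_transport_env()]: southern-area
#'   basin geometry, layer depth bounds (L1-L4 only), turnover times, ambient
#'   properties, and sediment-exchange parameters.
#' @export
transport_defaults <- function() {
  p <- paijanne_defaults()
  list(
    depth_bounds = p$depth_bounds[1:5],
    geometry = utils::modifyList(p$s_geometry, list(length = 3000)),
    turnover_h = p$turnover_h[1:3],
    epilimnion_temp = p$epilimnion_temp, hypolimnion_temp = p$hypolimnion_temp,
    ph = p$ph, ss_volume_fraction = p$ss_volume_fraction,
    ss_oc_fraction = p$ss_oc_fraction,
    sediment_oc = p$sediment_oc, sediment_thickness = p$sediment_thickness,
    sediment_porosity = p$sediment_porosity,
    mtc_diff = p$mtc_diff, u_dep = p$u_dep, u_res = p$u_res, u_bur = p$u_bur,
    gamma = p$gamma, t_ref = p$t_ref
  )
}

#' Build a plug-flow transport segment environment
#'
#' A single set of L1-L4 water layers with the southern-area cross-section,
#' through-flow advection at the given velocity, vertical mixing from the
#' packaged turnover times (scaled to the segment volume), and one bottom
#' sediment slab exchanging with L3 and L4. The stronger-wind variant uses
#' 3 cm/s and tenfold vertical mixing.
#'
#' @param velocity Water velocity, cm/s (> 0); 1 for the weak-wind and 3 for
#'   the stronger-wind variant.
#' @param vertical_mixing_factor Multiplier on all vertical mixing rates
#'   (10 for the stronger-wind variant).
#' @param segment_length Segment length, m (300 or 3000 in the packaged
#'   chain).
#' @param overrides Named list overriding [transport_defaults()].
#' @param chemicals,reactions As in [build_paijanne_ns()].
#' @return A validated [environment_spec()].
#' @export
build_transport_env <- function(velocity = 1, vertical_mixing_factor = 1,
                                segment_length = 3000, overrides = list(),
                                chemicals = default_chemicals(),
                                reactions = default_reactions()) {
  if (velocity <= 0) stop("velocity must be > 0")
  p <- check_overrides(transport_defaults(), overrides)
  p$geometry$length <- segment_length
  g <- p$geometry

  comps <- area_layers("TL", g, 4, p)
  a_L3 <- bed_strip_area(g, 1, 5)
  a_L4 <- bed_strip_area(g, 5, 9) + g$length * basin_width(g, 9)
  comps <- rbind(comps, compartment_spec(
    id = "TSED", medium = "bottom_sediment",
    volume = (a_L3 + a_L4) * p$sediment_thickness,
    temperature = p$hypolimnion_temp, ph = p$ph,
    oc_fraction = p$sediment_oc, porosity = p$sediment_porosity))

  v <- cms_to_mh(velocity)
  links <- list()
  for (i in 1:4) {
    gr <- v * layer_cross_section(g, p, i)
    links[[length(links) + 1]] <- flow_link("advection", "inflow",
                                            paste0("TL", i), rate = gr)
    links[[length(links) + 1]] <- flow_link("advection", paste0("TL", i),
                                            "outflow", rate = gr)
  }
  links <- do.call(rbind, links)
  links <- rbind(links,
                 area_mixing_links("TL", comps, 4, p,
                                   factor = vertical_mixing_factor),
                 sed_link(p, "TL3", "TSED", a_L3),
                 sed_link(p, "TL4", "TSED", a_L4))

  emis <- data.frame(compartment = character(), chemical = character(),
                     water_flow = numeric(), mol_h = numeric())
  environment_spec(comps, links, emis, chemicals, reactions,
                   options = list(gamma = p$gamma, t_ref = p$t_ref,
                                  scenario = "transport",
                                  velocity_cm_s = velocity,
                                  segment_length = segment_length,
                                  params = p))
}
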