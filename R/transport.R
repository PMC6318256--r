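# Plug-flow transport chain: serial quasi-steady application of a short
# transport environment, recursion to locate transformation-product peaks,
# sinking-average input preparation and the conjugate pseudo-chemical variant.

#' Extract a transport input from a lake-scenario result
#'
#' Collects the bulk water concentrations of the given compartments (ng/l)
#' into the layer-by-chemical matrix consumed by [run_segment()].
#'
#' @param result A `fate_result` from [solve_steady_state()].
#' @param compartments Water compartment ids, ordered surface to deep
#'   (default the southern layers SL1-SL4).
#' @param layer_ids Row names for the output (default TL1-TL4, matching the
#'   transport environment).
#' @return Numeric matrix, layers x chemicals, ng/l.
#' @export
transport_input <- function(result, compartments = paste0("SL", 1:4),
                            layer_ids = paste0("TL", seq_along(compartments))) {
  chems <- unique(result$table$chemical)
  m <- matrix(0, length(compartments), length(chems),
              dimnames = list(layer_ids, chems))
  for (i in seq_along(compartments)) {
    rows <- result$table[result$table$compartment == compartments[i], ]
    m[i, rows$chemical] <- rows$concentration
  }
  m
}

#' Sinking average of a layered concentration profile
#'
#' Emulates effluent sinking during transport: each layer's input is averaged
#' with the layer above it (`out[i] = (in[i] + in[i-1]) / 2`); the surface
#' layer is unchanged.
#'
#' @param input Layers x chemicals matrix, ordered surface to deep.
#' @return Matrix of the same shape.
#' @export
sinking_average <- function(input) {
  out <- input
  if (nrow(input) > 1)
    for (i in nrow(input):2) out[i, ] <- (input[i, ] + input[i - 1, ]) / 2
  out
}

# Boundary molar inflows (mol/h) equivalent to given layer concentrations.
boundary_inflow_from_conc <- function(env, input) {
  adv_in <- env$links[env$links$kind == "advection" &
                        env$links$source == "inflow", ]
  rows <- list()
  for (i in seq_len(nrow(input))) {
    layer <- rownames(input)[i]
    G <- adv_in$rate[adv_in$target == layer]
    if (!length(G)) stop("no boundary inflow link for layer ", layer)
    for (ch in colnames(input)) {
      mw <- env$chemicals[[ch]]$molecular_weight
      rows[[length(rows) + 1]] <- data.frame(
        compartment = layer, chemical = ch,
        mol_h = G * input[i, ch] * 1e-6 / mw, # ng/l -> g/m3 is 1e-6
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run one quasi-steady transport segment
#'
#' Converts the layer input concentrations into boundary advective molar
#' inflows, solves the segment at steady state and returns the outlet-layer
#' concentrations (the segment's steady-state water concentrations).
#'
#' @param env A transport [environment_spec()] from [build_transport_env()].
#' @param input Layers x chemicals matrix, ng/l (rows must match the
#'   environment's water layers).
#' @return List: `output` (matrix like `input`), `result` (the full
#'   `fate_result`).
#' @export
run_segment <- function(env, input) {
  missing_ch <- setdiff(colnames(input), names(env$chemicals))
  if (length(missing_ch))
    stop("input chemicals not in environment: ",
         paste(missing_ch, collapse = ", "))
  input <- pad_input(env, input)
  bi <- boundary_inflow_from_conc(env, input)
  res <- solve_steady_state(env, boundary_inflow = bi)
  out <- input
  for (i in seq_len(nrow(input))) {
    rows <- res$table[res$table$compartment == rownames(input)[i], ]
    out[i, rows$chemical] <- rows$concentration
  }
  list(output = out, result = res)
}

# Extend an input matrix with zero columns for chemicals the environment
# tracks but the input does not mention (e.g. products formed downstream).
pad_input <- function(env, input) {
  extra <- setdiff(names(env$chemicals), colnames(input))
  if (!length(extra)) return(input)
  cbind(input, matrix(0, nrow(input), length(extra),
                      dimnames = list(rownames(input), extra)))
}

#' Recursive transport until transformation products plateau
#'
#' Applies the segment environment repeatedly, each time feeding the previous
#' output back in, until every transformation product's peak water
#' concentration changes by less than `rel_tol` between consecutive segments
#' (or a hard segment cap is reached). Records each chemical's concentration
#' maximum: at which cumulative distance it occurs and the corresponding
#' travel time.
#'
#' @param env Transport environment (its `segment_length` and velocity set
#'   the distance/time bookkeeping).
#' @param input Initial layers x chemicals matrix, ng/l.
#' @param rel_tol Plateau tolerance (default 0.01).
#' @param max_segments Hard cap on segments (default 50).
#' @param tp_ids Chemicals treated as transformation products for the plateau
#'   test; defaults to every chemical that appears as a reaction product.
#' @return Object of class `transport_chain`: `trajectory` (segment,
#'   distance_m, chemical, conc_max ng/l, water mass mol), `peaks` (chemical,
#'   peak_distance_m, peak_conc, travel_time_h), `segments` (list of output
#'   matrices), `converged`.
#' @export
run_until_plateau <- function(env, input, rel_tol = 0.01, max_segments = 50,
                              tp_ids = NULL) {
  if (rel_tol <= 0) stop("rel_tol must be > 0")
  input <- pad_input(env, input)
  if (is.null(tp_ids))
    tp_ids <- intersect(unique(env$reactions$product), colnames(input))
  seg_len <- env$options$segment_length
  vel_mh <- cms_to_mh(env$options$velocity_cm_s)
  chems <- colnames(input)
  traj <- list(); outputs <- list()
  # segment 0 = the incoming profile
  traj[[1]] <- data.frame(segment = 0, distance_m = 0, chemical = chems,
                          conc_max = apply(input, 2, max),
                          water_mass_mol = NA_real_, stringsAsFactors = FALSE)
  cur <- input; converged <- FALSE
  for (s in seq_len(max_segments)) {
    step <- run_segment(env, cur)
    wtab <- step$result$table[step$result$table$medium == "surface_water", ]
    mass <- vapply(chems, function(ch)
      sum(wtab$mass_mol[wtab$chemical == ch]), numeric(1))
    out <- step$output
    traj[[s + 1]] <- data.frame(segment = s, distance_m = s * seg_len,
                                chemical = chems,
                                conc_max = apply(out, 2, max),
                                water_mass_mol = mass,
                                stringsAsFactors = FALSE)
    outputs[[s]] <- out
    prev_max <- apply(cur, 2, max)[tp_ids]
    new_max <- apply(out, 2, max)[tp_ids]
    denom <- pmax(new_max, prev_max)
    change <- ifelse(denom > 0, abs(new_max - prev_max) / denom, 0)
    cur <- out
    if (s > 1 && all(change < rel_tol)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("transport recursion did not plateau within ", max_segments,
            " segments; returning the partial chain")
  trajectory <- do.call(rbind, traj)
  peaks <- do.call(rbind, lapply(chems, function(ch) {
    tr <- trajectory[trajectory$chemical == ch, ]
    i <- which.max(tr$conc_max)
    data.frame(chemical = ch, peak_distance_m = tr$distance_m[i],
               peak_conc = tr$conc_max[i],
               travel_time_h = tr$distance_m[i] / vel_mh,
               stringsAsFactors = FALSE)
  }))
  structure(list(trajectory = trajectory, peaks = peaks, segments = outputs,
                 converged = converged, tp_ids = tp_ids, env = env),
            class = "transport_chain")
}

#' @export
print.transport_chain <- function(x, ...) {
  n_seg <- max(x$trajectory$segment)
  cat("<transport_chain>", n_seg, "segments x",
      x$env$options$segment_length, "m",
      if (x$converged) "(plateaued)" else "(cap reached)", "\n")
  cat("concentration peaks:\n")
  print(format(x$peaks, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Modal transformation-product peak distance
#'
#' The most common peak distance across the transformation products of a
#' chain (ties broken by the mean of the tied modes); chemicals whose peak
#' sits at distance 0 (monotone decay, no downstream maximum) are excluded.
#'
#' @param chain A `transport_chain`.
#' @return Distance in metres.
#' @export
modal_tp_peak_distance <- function(chain) {
  pk <- chain$peaks[chain$peaks$chemical %in% chain$tp_ids, ]
  d <- pk$peak_distance_m[pk$peak_distance_m > 0]
  if (!length(d)) return(0)
  tab <- table(d)
  mean(as.numeric(names(tab)[tab == max(tab)]))
}

#' Add a deconjugating conjugate pseudo-chemical
#'
#' Registers a conjugate pool of `parent` in the environment: a pseudo-
#' chemical with the parent's partitioning properties and a first-order
#' deconjugation reaction back to the parent (yield 1). Transport inputs are
#' augmented with [conjugate_input()] at `conc_factor` times the parent's
#' concentration.
#'
#' @param env An [environment_spec()].
#' @param parent Parent chemical id (default `"IBU"`).
#' @param conc_factor Initial conjugate concentration as a multiple of the
#'   parent's input (default 3; stored on the environment).
#' @param half_life Deconjugation half-life, hours (default 2).
#' @return The augmented environment.
#' @export
add_conjugate <- function(env, parent = "IBU", conc_factor = 3,
                          half_life = 2) {
  if (!parent %in% names(env$chemicals)) stop("unknown parent: ", parent)
  id <- paste0(parent, "-CONJ")
  if (id %in% names(env$chemicals))
    stop("conjugate pseudo-chemical already present: ", id)
  env$chemicals[[id]] <- conjugate_spec(env$chemicals[[parent]], id)
  env$reactions <- rbind(env$reactions,
                         data.frame(parent = id, product = parent,
                                    kind = "deconjugation",
                                    half_life_h = half_life,
                                    stringsAsFactors = FALSE))
  class(env$reactions) <- c("reaction_table", "data.frame")
  env$options$conjugate <- list(id = id, parent = parent,
                                conc_factor = conc_factor)
  env
}

#' Augment a transport input with the registered conjugate
#'
#' @param env Environment returned by [add_conjugate()].
#' @param input Layers x chemicals matrix, ng/l.
#' @return Matrix with the conjugate column appended (conc_factor x parent).
#' @export
conjugate_input <- function(env, input) {
  cj <- env$options$conjugate
  if (is.null(cj)) return(input)
  if (cj$id %in% colnames(input)) return(input)
  add <- matrix(cj$conc_factor * input[, cj$parent], ncol = 1,
                dimnames = list(rownames(input), cj$id))
  cbind(input, add)
}
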