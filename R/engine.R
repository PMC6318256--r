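# Level III fugacity engine: Z values, D values, per-chain linear systems,
# steady-state solve, flux ledger, and a dynamic integrator used as a
# verification oracle.

#' Water fugacity capacity
#'
#' Nominal water-phase capacity (aquivalence-style normalization). With no air
#' compartment in the system the absolute scale of Z is arbitrary: every
#' observable output (concentrations, masses, flux ratios) is invariant to
#' this constant, which is therefore fixed at 1 by default and only exposed so
#' the invariance can be demonstrated.
#'
#' @param chem A [chemical_spec()] (unused; kept for interface symmetry).
#' @param env Optional [environment_spec()] whose `options$z_water` supplies
#'   the constant.
#' @return Fugacity capacity, mol m-3 Pa-1.
#' @export
z_water <- function(chem = NULL, env = NULL) {
  if (!is.null(env)) env$options$z_water else 1
}

#' Solids fugacity capacity
#'
#' Sorption capacity of a solid phase (suspended or bed-sediment solids):
#' `Z_solids = Z_water * oc_fraction * Koc * solids_density` with Koc in l/kg
#' and density in kg/l.
#'
#' @param chem A [chemical_spec()].
#' @param ctx A [property_context()] for the host compartment.
#' @param oc_fraction Organic-carbon mass fraction of the solids.
#' @param solids_density kg/l.
#' @param zw Water capacity the solids capacity is scaled from.
#' @return Fugacity capacity, mol m-3 Pa-1.
#' @export
z_solids <- function(chem, ctx, oc_fraction, solids_density = 2.4, zw = 1) {
  if (oc_fraction < 0 || oc_fraction > 1) stop("oc_fraction outside [0,1]")
  zw * oc_fraction * koc(chem, ctx) * solids_density
}

#' Bulk fugacity capacity of a compartment
#'
#' Volume-weighted sum of phase capacities: for water,
#' `(1 - phi_ss) Z_water + phi_ss Z_ss-solids`; for sediment,
#' `porosity Z_water + (1 - porosity) Z_sed-solids`.
#'
#' @param comp One compartment row of an [environment_spec()].
#' @param chem A [chemical_spec()].
#' @param env The [environment_spec()] (supplies `z_water` and solids
#'   density).
#' @return Fugacity capacity, mol m-3 Pa-1.
#' @export
z_bulk <- function(comp, chem, env) {
  ctx <- property_context(comp$temperature, comp$ph)
  zw <- z_water(chem, env)
  rho <- env$options$solids_density
  if (comp$medium == "surface_water") {
    phi <- comp$ss_volume_fraction
    (1 - phi) * zw + phi * z_solids(chem, ctx, comp$ss_oc_fraction, rho, zw)
  } else {
    comp$porosity * zw +
      (1 - comp$porosity) * z_solids(chem, ctx, comp$oc_fraction, rho, zw)
  }
}

# Precompute capacities for all compartments x chemicals of a chain.
# Returns list of matrices [n_comp x n_chem]: zb (bulk), zsolid (the
# compartment's own solids phase: suspended for water, bed for sediment).
capacity_tables <- function(env, chem_ids) {
  comp <- env$compartments
  n <- nrow(comp); m <- length(chem_ids)
  zb <- zsolid <- matrix(0, n, m, dimnames = list(comp$id, chem_ids))
  rho <- env$options$solids_density
  for (i in seq_len(n)) {
    ctx <- property_context(comp$temperature[i], comp$ph[i])
    for (j in seq_len(m)) {
      chem <- env$chemicals[[chem_ids[j]]]
      zw <- z_water(chem, env)
      oc <- if (comp$medium[i] == "surface_water")
        comp$ss_oc_fraction[i] else comp$oc_fraction[i]
      zsolid[i, j] <- z_solids(chem, ctx, oc, rho, zw)
      zb[i, j] <- z_bulk(comp[i, ], chem, env)
    }
  }
  list(zb = zb, zsolid = zsolid, zw = env$options$z_water)
}

# Which reaction kinds act in a compartment medium, and their rate multiplier.
applicable_kinds <- function(comp_row) {
  if (comp_row$medium == "surface_water")
    c(photo = comp_row$photolysis_multiplier, deconjugation = 1)
  else
    c(bio = 1)
}

#' Assemble the steady-state linear system of one reaction chain
#'
#' Builds the dense `n*m x n*m` matrix `A` and emission vector `b` of
#' `A f = b` for one chain of inter-reacting chemicals over all compartments.
#' Unknowns are ordered compartment-major; the diagonal holds the summed loss
#' D values of each compartment-chemical (advection out, mixing out, sediment
#' exchange out, burial, total reaction), off-diagonal gains carry negative
#' signs: transport links within a chemical and parent-to-product
#' transformation D values (`D_reaction * yield`) within a compartment.
#'
#' @param env A validated [environment_spec()].
#' @param chain Character vector of chemical ids closed under the product
#'   relation (one element of [reaction_chains()]).
#' @param boundary_inflow Optional `data.frame(compartment, chemical, mol_h)`
#'   of advective boundary inputs added to `b` (used by the transport chain).
#' @return List with `A`, `b`, `index` (data.frame compartment/chemical per
#'   unknown), and `ledger` (D values; flows are filled in after solving).
#' @export
assemble_system <- function(env, chain, boundary_inflow = NULL) {
  comp <- env$compartments
  n <- nrow(comp); m <- length(chain)
  caps <- capacity_tables(env, chain)
  idx <- function(ci, cj) (ci - 1L) * m + cj
  A <- matrix(0, n * m, n * m)
  b <- numeric(n * m)
  index <- data.frame(compartment = rep(comp$id, each = m),
                      chemical = rep(chain, times = n),
                      stringsAsFactors = FALSE)
  led <- list()
  add_led <- function(chemical, kind, source, target, D, si = NA, ti = NA) {
    led[[length(led) + 1L]] <<- data.frame(
      chemical = chemical, kind = kind, source = source, target = target,
      D = D, src_idx = si, stringsAsFactors = FALSE)
  }
  loss <- function(ci, cj, D) A[idx(ci, cj), idx(ci, cj)] <<-
    A[idx(ci, cj), idx(ci, cj)] + D
  gain <- function(ti, tj, si, sj, D) A[idx(ti, tj), idx(si, sj)] <<-
    A[idx(ti, tj), idx(si, sj)] - D

  cid <- function(id) match(id, comp$id)

  # transport D values
  for (r in seq_len(nrow(env$links))) {
    l <- env$links[r, ]
    if (l$kind == "advection") {
      if (l$source == "inflow") next # clean boundary water carries nothing
      si <- cid(l$source)
      for (j in seq_len(m)) {
        D <- l$rate * caps$zb[si, j]
        loss(si, j, D)
        if (l$target %in% comp$id) gain(cid(l$target), j, si, j, D)
        add_led(chain[j], "advection", l$source, l$target, D, idx(si, j))
      }
    } else if (l$kind == "mixing") {
      si <- cid(l$source); ti <- cid(l$target)
      for (j in seq_len(m)) {
        D1 <- l$rate * caps$zb[si, j]
        D2 <- l$rate * caps$zb[ti, j]
        loss(si, j, D1); gain(ti, j, si, j, D1)
        loss(ti, j, D2); gain(si, j, ti, j, D2)
        add_led(chain[j], "mixing", l$source, l$target, D1, idx(si, j))
        add_led(chain[j], "mixing", l$target, l$source, D2, idx(ti, j))
      }
    } else { # sediment_exchange; orient water -> sediment
      a <- cid(l$source); bb <- cid(l$target)
      if (comp$medium[a] == "bottom_sediment") { tmp <- a; a <- bb; bb <- tmp }
      for (j in seq_len(m)) {
        zw <- caps$zw
        D_diff <- l$area * l$mtc_diff * zw
        D_dep <- l$area * l$u_dep * caps$zsolid[a, j]
        D_res <- l$area * l$u_res * caps$zsolid[bb, j]
        D_bur <- l$area * l$u_bur * caps$zsolid[bb, j]
        loss(a, j, D_diff + D_dep); gain(bb, j, a, j, D_diff + D_dep)
        loss(bb, j, D_diff + D_res); gain(a, j, bb, j, D_diff + D_res)
        loss(bb, j, D_bur)
        add_led(chain[j], "sed_diffusion", comp$id[a], comp$id[bb], D_diff,
                idx(a, j))
        add_led(chain[j], "deposition", comp$id[a], comp$id[bb], D_dep,
                idx(a, j))
        add_led(chain[j], "sed_diffusion", comp$id[bb], comp$id[a], D_diff,
                idx(bb, j))
        add_led(chain[j], "resuspension", comp$id[bb], comp$id[a], D_res,
                idx(bb, j))
        add_led(chain[j], "burial", comp$id[bb], "buried", D_bur, idx(bb, j))
      }
    }
  }

  # reaction D values
  scheme <- reaction_scheme(env$reactions)
  for (ci in seq_len(n)) {
    kinds <- applicable_kinds(comp[ci, ])
    tcorr <- exp(env$options$gamma * (comp$temperature[ci] - env$options$t_ref))
    for (j in seq_len(m)) {
      for (kk in seq_along(kinds)) {
        kind <- names(kinds)[kk]; mult <- kinds[[kk]]
        sch <- scheme[[paste(chain[j], kind, sep = "|")]]
        if (is.null(sch) || mult == 0) next
        k_tot <- rate_from_half_life(sch$total_half_life) * mult * tcorr
        D_tot <- k_tot * comp$volume[ci] * caps$zb[ci, j]
        if (D_tot == 0) next
        loss(ci, j, D_tot)
        for (pp in seq_along(sch$products)) {
          pj <- match(sch$products[pp], chain)
          if (is.na(pj)) stop("chain not closed: product ", sch$products[pp],
                              " of ", chain[j], " missing")
          Dp <- sch$yields[pp] * D_tot
          gain(ci, pj, ci, j, Dp)
          add_led(chain[j], paste0("reaction_", kind), comp$id[ci],
                  sch$products[pp], Dp, idx(ci, j))
        }
        if (sch$sink_yield > 1e-12)
          add_led(chain[j], paste0("reaction_", kind), comp$id[ci], "sink",
                  sch$sink_yield * D_tot, idx(ci, j))
      }
    }
  }

  # emissions and boundary inflows
  emis <- env$emissions
  for (r in seq_len(nrow(emis))) {
    j <- match(emis$chemical[r], chain)
    if (is.na(j)) next
    b[idx(cid(emis$compartment[r]), j)] <- b[idx(cid(emis$compartment[r]), j)] +
      emis$mol_h[r]
  }
  if (!is.null(boundary_inflow)) {
    for (r in seq_len(nrow(boundary_inflow))) {
      j <- match(boundary_inflow$chemical[r], chain)
      if (is.na(j)) next
      ci <- cid(boundary_inflow$compartment[r])
      b[idx(ci, j)] <- b[idx(ci, j)] + boundary_inflow$mol_h[r]
    }
  }

  dg <- diag(A)
  if (any(dg <= 0)) {
    bad <- which(dg <= 0)[1]
    stop("structurally singular system: no loss path for ",
         index$compartment[bad], " / ", index$chemical[bad])
  }
  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(chemical = character(), kind = character(), source = character(),
               target = character(), D = numeric(), src_idx = integer())
  list(A = A, b = b, index = index, ledger = ledger, caps = caps)
}

#' Solve the steady state of a model environment
#'
#' Groups the scenario's chemicals into reaction chains, assembles each
#' chain's linear system and solves it by dense direct factorization.
#' Concentrations are reported as bulk water concentration in ng/l for water
#' compartments and dry-weight sorbed concentration in ng/g for sediments.
#'
#' @param env A validated [environment_spec()].
#' @param boundary_inflow Optional `data.frame(compartment, chemical, mol_h)`
#'   of advective boundary inputs (transport chaining).
#' @return Object of class `fate_result` with elements `table` (one row per
#'   compartment-chemical: fugacity, concentration + unit, mass in mol),
#'   `ledger` (every D flow evaluated at the solution, plus emissions), and
#'   `residuals` (per-chemical mass-balance residuals).
#' @export
solve_steady_state <- function(env, boundary_inflow = NULL) {
  chains <- reaction_chains(names(env$chemicals), env$reactions)
  comp <- env$compartments
  tabs <- list(); leds <- list()
  for (chain in chains) {
    sys <- assemble_system(env, chain, boundary_inflow)
    f <- tryCatch(solve(sys$A, sys$b), error = function(e)
      stop("singular steady-state system for chain [",
           paste(chain, collapse = ", "), "]: ", conditionMessage(e)))
    scale <- max(abs(f), 1e-300)
    if (any(f < -1e-9 * scale))
      stop("internal inconsistency: negative fugacities in chain [",
           paste(chain, collapse = ", "), "]")
    f[f < 0] <- 0
    ci <- match(sys$index$compartment, comp$id)
    cj <- match(sys$index$chemical, chain)
    mw <- vapply(sys$index$chemical,
                 function(id) env$chemicals[[id]]$molecular_weight, numeric(1))
    zbv <- sys$caps$zb[cbind(ci, cj)]
    zsv <- sys$caps$zsolid[cbind(ci, cj)]
    is_water <- comp$medium[ci] == "surface_water"
    conc <- ifelse(is_water,
                   f * zbv * mw * 1e6,                    # ng/l bulk water
                   f * zsv * mw * 1000 / env$options$solids_density) # ng/g dry
    tabs[[length(tabs) + 1]] <- data.frame(
      compartment = sys$index$compartment, chemical = sys$index$chemical,
      medium = comp$medium[ci],
      fugacity = f, concentration = conc,
      unit = ifelse(is_water, "ng/l", "ng/g dry"),
      mass_mol = f * zbv * comp$volume[ci],
      stringsAsFactors = FALSE)
    led <- sys$ledger
    led$flow_mol_h <- led$D * f[led$src_idx]
    led$src_idx <- NULL
    leds[[length(leds) + 1]] <- led
  }
  ledger <- do.call(rbind, leds)
  emis <- env$emissions
  if (nrow(emis)) {
    ledger <- rbind(ledger, data.frame(
      chemical = emis$chemical, kind = "emission", source = "emission",
      target = emis$compartment, D = NA_real_, flow_mol_h = emis$mol_h,
      stringsAsFactors = FALSE))
  }
  if (!is.null(boundary_inflow) && nrow(boundary_inflow)) {
    ledger <- rbind(ledger, data.frame(
      chemical = boundary_inflow$chemical, kind = "boundary_inflow",
      source = "inflow", target = boundary_inflow$compartment, D = NA_real_,
      flow_mol_h = boundary_inflow$mol_h, stringsAsFactors = FALSE))
  }
  res <- structure(list(env = env, chains = chains,
                        table = do.call(rbind, tabs), ledger = ledger),
                   class = "fate_result")
  res$residuals <- mass_balance_report(res)
  res
}

#' Mass-balance ledger summary
#'
#' For every chemical: total inputs (emissions, boundary inflows and
#' transformation gains from parents) against total outputs (boundary
#' outflows, reaction losses and burial), with the relative residual. A
#' residual above 1e-6 is flagged with a warning.
#'
#' @param result A `fate_result`.
#' @return `data.frame` with one row per chemical.
#' @export
mass_balance_report <- function(result) {
  led <- result$ledger
  chems <- unique(result$table$chemical)
  out <- do.call(rbind, lapply(chems, function(ch) {
    l <- led[led$chemical == ch, , drop = FALSE]
    # transformation gains are logged under the parent's chemical id
    formed <- sum(led$flow_mol_h[startsWith(led$kind, "reaction_") &
                                   led$target == ch])
    inputs <- sum(l$flow_mol_h[l$kind %in% c("emission", "boundary_inflow")]) +
      formed
    losses <- sum(l$flow_mol_h[l$kind == "advection" & l$target == "outflow"]) +
      sum(l$flow_mol_h[startsWith(l$kind, "reaction_")]) +
      sum(l$flow_mol_h[l$kind == "burial"])
    resid <- if (max(inputs, losses) > 0)
      abs(inputs - losses) / max(inputs, losses) else 0
    data.frame(chemical = ch, inputs_mol_h = inputs, losses_mol_h = losses,
               residual = resid, stringsAsFactors = FALSE)
  }))
  if (any(out$residual > 1e-6))
    warning("mass-balance residual above 1e-6 for: ",
            paste(out$chemical[out$residual > 1e-6], collapse = ", "))
  out
}

#' @export
print.fate_result <- function(x, n = 10, ...) {
  cat("<fate_result>", length(unique(x$table$compartment)), "compartments x",
      length(unique(x$table$chemical)), "chemicals\n")
  tab <- x$table[order(-x$table$concentration), ]
  cat("top concentrations:\n")
  print(format(utils::head(tab[, c("compartment", "chemical",
                                   "concentration", "unit")], n),
               digits = 3), row.names = FALSE)
  cat(sprintf("max mass-balance residual: %.2e\n", max(x$residuals$residual)))
  invisible(x)
}

#' @export
summary.fate_result <- function(object, ...) {
  cat("Steady-state mass balance by chemical (mol/h):\n")
  print(format(object$residuals, digits = 4), row.names = FALSE)
  invisible(object$residuals)
}

#' Extract concentrations from a result
#'
#' @param result A `fate_result`.
#' @param chemicals,compartments Optional filters.
#' @return `data.frame` of compartment, chemical, concentration, unit.
#' @export
concentrations <- function(result, chemicals = NULL, compartments = NULL) {
  tab <- result$table
  if (!is.null(chemicals)) tab <- tab[tab$chemical %in% chemicals, ]
  if (!is.null(compartments)) tab <- tab[tab$compartment %in% compartments, ]
  tab[, c("compartment", "chemical", "concentration", "unit")]
}

#' Dynamic integration of the mass balance (verification oracle)
#'
#' Integrates `V Z df/dt = b - A f` per reaction chain with a stiff ODE
#' solver. Intended as an independent check that the steady-state solution is
#' the long-time limit of the dynamics, and of equilibration timescales; not a
#' production Level IV feature.
#'
#' @param env A validated [environment_spec()].
#' @param duration Hours to integrate.
#' @param n_out Number of output time points.
#' @param initial_fugacities Optional named vector
#'   (`"<compartment>|<chemical>"`) of starting fugacities; default zero.
#' @param boundary_inflow As in [solve_steady_state()].
#' @return `data.frame` time series: time_h, compartment, chemical, fugacity.
#' @export
dynamic_integrate <- function(env, duration, n_out = 60,
                              initial_fugacities = NULL,
                              boundary_inflow = NULL) {
  chains <- reaction_chains(names(env$chemicals), env$reactions)
  comp <- env$compartments
  out <- list()
  for (chain in chains) {
    sys <- assemble_system(env, chain, boundary_inflow)
    ci <- match(sys$index$compartment, comp$id)
    cj <- match(sys$index$chemical, chain)
    vz <- comp$volume[ci] * sys$caps$zb[cbind(ci, cj)]
    key <- paste(sys$index$compartment, sys$index$chemical, sep = "|")
    f0 <- numeric(length(key))
    if (!is.null(initial_fugacities)) {
      hit <- match(key, names(initial_fugacities))
      f0[!is.na(hit)] <- initial_fugacities[hit[!is.na(hit)]]
    }
    deriv <- function(t, f, parms) list((sys$b - sys$A %*% f) / vz)
    times <- seq(0, duration, length.out = n_out + 1)
    sol <- deSolve::lsoda(f0, times, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0)
      stop("dynamic integration failed (stiffness/step-size problem)")
    for (r in seq_len(nrow(sol))) {
      out[[length(out) + 1]] <- data.frame(
        time_h = unname(sol[r, 1]), compartment = sys$index$compartment,
        chemical = sys$index$chemical,
        fugacity = as.numeric(sol[r, -1]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
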