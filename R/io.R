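# Scenario (de)serialization and the command-line interface.

packaged_scenarios <- c("paijanne_ns", "transport_weak", "transport_strong",
                        "toy_two_box")

#' Load a scenario by packaged name or file path
#'
#' A scenario file is YAML, either a builder form (`builder:` plus `params:`,
#' how the packaged lake and transport scenarios are shipped) or an explicit
#' form with sections `chemicals`, `reactions`, `compartments`, `links`,
#' `emissions`, `options`. Validation problems are reported exhaustively.
#'
#' @param name Packaged scenario name (`"paijanne_ns"`, `"transport_weak"`,
#'   `"transport_strong"`, `"toy_two_box"`) or a path to a YAML file.
#' @param overrides Named list forwarded to the builder (builder form only).
#' @return A validated [environment_spec()].
#' @export
load_scenario <- function(name, overrides = list()) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".yaml"), package = "lakefate")
  if (!nzchar(path) || !file.exists(path))
    stop("scenario not found: ", name, " (packaged: ",
         paste(packaged_scenarios, collapse = ", "), ")")
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$builder)) {
    params <- utils::modifyList(as.list(doc$params %||% list()), overrides)
    return(switch(doc$builder,
      paijanne_ns = build_paijanne_ns(normalize_builder_params(params)),
      transport = {
        vel <- params$velocity %||% 1
        vmf <- params$vertical_mixing_factor %||% 1
        len <- params$segment_length %||% 3000
        rest <- params[setdiff(names(params),
                               c("velocity", "vertical_mixing_factor",
                                 "segment_length"))]
        build_transport_env(vel, vmf, len, overrides = rest)
      },
      stop("unknown builder: ", doc$builder)))
  }
  parse_explicit_scenario(doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML turns named numeric vectors into lists; restore the ones the builder
# expects as vectors.
normalize_builder_params <- function(params) {
  for (nm in c("effluent_conc_ug_l")) {
    if (!is.null(params[[nm]])) params[[nm]] <- unlist(params[[nm]])
  }
  for (nm in c("turnover_h", "depth_bounds")) {
    if (!is.null(params[[nm]])) params[[nm]] <- as.numeric(unlist(params[[nm]]))
  }
  params
}

parse_explicit_scenario <- function(doc) {
  errs <- character()
  need <- c("compartments", "links", "emissions")
  for (s in need) if (is.null(doc[[s]]))
    errs <- c(errs, paste0("missing section: ", s))
  if (length(errs)) stop("invalid scenario file:\n  - ",
                         paste(errs, collapse = "\n  - "))

  chems <- if (is.null(doc$chemicals) || identical(doc$chemicals, "default"))
    default_chemicals()
  else {
    specs <- lapply(doc$chemicals, function(r)
      chemical_spec(r$id, r$molecular_weight, r$water_solubility, r$log_kow,
                    pka = r$pka %||% NA_real_,
                    dissociation_class = r$dissociation_class %||% "neutral",
                    koc_kow_ratio = r$koc_kow_ratio,
                    property_mode = r$property_mode %||% "at_ph7",
                    inherited = as.character(r$inherited %||% character())))
    stats::setNames(specs, vapply(specs, `[[`, "", "id"))
  }
  reacts <- if (is.null(doc$reactions) || identical(doc$reactions, "default"))
    default_reactions()
  else if (length(doc$reactions) == 0)
    reaction_table(character(), character(), character(), numeric())
  else {
    rr <- do.call(rbind, lapply(doc$reactions, as.data.frame))
    reaction_table(rr$parent, rr$product, rr$kind, rr$half_life_h)
  }
  comps <- do.call(rbind, lapply(doc$compartments, function(r)
    do.call(compartment_spec, r)))
  links <- do.call(rbind, lapply(doc$links, function(r)
    do.call(flow_link, r)))
  emis <- if (length(doc$emissions))
    do.call(rbind, lapply(doc$emissions, function(r) {
      r$molecular_weight <- if (!is.null(r$concentration))
        chems[[r$chemical]]$molecular_weight else NA
      do.call(emission_spec, r)
    }))
  else data.frame(compartment = character(), chemical = character(),
                  water_flow = numeric(), mol_h = numeric())
  environment_spec(comps, links, emis, chems, reacts,
                   options = as.list(doc$options %||% list()))
}

#' Write a scenario to an explicit YAML file
#'
#' Serializes the environment in the explicit section form accepted by
#' [load_scenario()]; loading the file back reproduces an equal scenario.
#'
#' @param env An [environment_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(env, path) {
  df_records <- function(df) lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    r[!vapply(r, function(v) is.na(v) || (is.numeric(v) && !is.finite(v)),
              logical(1))]
  })
  comp <- env$compartments
  comp_rec <- lapply(seq_len(nrow(comp)), function(i) {
    r <- as.list(comp[i, ])
    r$volume <- comp$volume[i]
    r[c("id", "medium", "volume", "temperature", "ph", "oc_fraction",
        "porosity", "ss_volume_fraction", "ss_oc_fraction",
        "photolysis_multiplier")]
  })
  chem_rec <- lapply(env$chemicals, function(s) {
    r <- unclass(s)
    r$inherited <- as.list(r$inherited)
    r[c("id", "molecular_weight", "water_solubility", "log_kow", "pka",
        "dissociation_class", "koc_kow_ratio", "property_mode", "inherited")]
  })
  doc <- list(
    chemicals = unname(chem_rec),
    reactions = df_records(as.data.frame(env$reactions)),
    compartments = comp_rec,
    links = df_records(env$links),
    emissions = df_records(env$emissions),
    options = env$options[vapply(env$options, function(v)
      is.numeric(v) && length(v) == 1, logical(1))]
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Writes `concentrations.csv` (one row per compartment-chemical),
#' `fluxes.csv` (the D-value ledger evaluated at the solution) and
#' `mass_balance.csv` (per-chemical residuals).
#'
#' @param result A `fate_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- function(df, cols) { df[cols] <- lapply(df[cols], signif, 6); df }
  utils::write.csv(sig(result$table, c("fugacity", "concentration",
                                       "mass_mol")),
                   file.path(dir, "concentrations.csv"), row.names = FALSE)
  utils::write.csv(sig(result$ledger, c("D", "flow_mol_h")),
                   file.path(dir, "fluxes.csv"), row.names = FALSE)
  utils::write.csv(sig(result$residuals,
                       c("inputs_mol_h", "losses_mol_h", "residual")),
                   file.path(dir, "mass_balance.csv"), row.names = FALSE)
  invisible(dir)
}

parse_cli_overrides <- function(kvs) {
  out <- list()
  for (kv in kvs) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad --override (need key=value): ", kv)
    out[[parts[1]]] <- utils::type.convert(parts[2], as.is = TRUE)
  }
  out
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{run <scenario>}{solve the steady state and write result tables.}
#'   \item{transport <scenario>}{run the packaged transport chain; with
#'     `--plateau` iterate 3-km segments until transformation products
#'     plateau and write the peak summary; with `--conjugate` include the
#'     parent-conjugate pseudo-chemical.}
#'   \item{sensitivity <scenario>}{run the perturbation list in
#'     `--perturbations <yaml>` (default: packaged survey) and write the
#'     report.}
#'   \item{validate <scenario>}{run the invariant suite (mass balance,
#'     linearity in emissions, normalization invariance) on the scenario.}
#' }
#' Common flags: `--out <dir>` (default `.`), repeatable
#' `--override key=value` builder overrides.
#'
#' @param args Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
lakefate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: lakefate <run|transport|sensitivity|validate>",
                 "<scenario> [--out DIR] [--override k=v]...",
                 "[--plateau] [--conjugate] [--perturbations FILE]")
  status <- tryCatch({
    if (length(args) < 2) stop(usage)
    cmd <- args[1]; scenario <- args[2]; rest <- args[-(1:2)]
    out_dir <- "."
    overrides <- character(); plateau <- FALSE; conjugate <- FALSE
    pert_file <- NULL
    i <- 1
    while (i <= length(rest)) {
      a <- rest[i]
      if (a == "--out") { out_dir <- rest[i + 1]; i <- i + 2 }
      else if (a == "--override") { overrides <- c(overrides, rest[i + 1]); i <- i + 2 }
      else if (a == "--plateau") { plateau <- TRUE; i <- i + 1 }
      else if (a == "--conjugate") { conjugate <- TRUE; i <- i + 1 }
      else if (a == "--perturbations") { pert_file <- rest[i + 1]; i <- i + 2 }
      else stop("unknown argument: ", a, "\n", usage)
    }
    ov <- parse_cli_overrides(overrides)

    if (cmd == "run") {
      env <- load_scenario(scenario, ov)
      res <- solve_steady_state(env)
      write_results(res, out_dir)
      print(res)
      message("results written to ", normalizePath(out_dir))
    } else if (cmd == "transport") {
      env <- load_scenario(scenario, ov)
      if (conjugate) env <- add_conjugate(env)
      ns <- solve_steady_state(load_scenario("paijanne_ns"))
      input <- sinking_average(transport_input(ns))
      input <- conjugate_input(env, input)
      if (plateau) {
        chain <- run_until_plateau(env, input)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(chain$trajectory,
                         file.path(out_dir, "trajectory.csv"),
                         row.names = FALSE)
        utils::write.csv(chain$peaks, file.path(out_dir, "peaks.csv"),
                         row.names = FALSE)
        print(chain)
      } else {
        seg <- run_segment(env, input)
        write_results(seg$result, out_dir)
        print(seg$result)
      }
    } else if (cmd == "sensitivity") {
      env <- load_scenario(scenario, ov)
      if (is.null(pert_file))
        pert_file <- system.file("extdata", "perturbations_default.yaml",
                                 package = "lakefate", mustWork = TRUE)
      perts <- lapply(yaml::read_yaml(pert_file), function(r) {
        if (!is.null(r$value) && is.list(r$value))
          r$value <- unlist(r$value)
        do.call(perturbation, r)
      })
      rep <- run_sensitivity(env, perts)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rep$table, file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
      print(rep)
      if (length(rep$failures)) stop("some perturbations failed")
    } else if (cmd == "validate") {
      env <- load_scenario(scenario, ov)
      res <- solve_steady_state(env)
      resid <- max(res$residuals$residual)
      if (resid > 1e-9) stop("mass-balance residual too large: ", resid)
      if (nrow(env$emissions)) {
        env2 <- apply_perturbation(env, perturbation("emission_scale", 2))
        res2 <- solve_steady_state(env2)
        if (max(abs(res2$table$concentration - 2 * res$table$concentration) /
                  pmax(res2$table$concentration, 1e-300)) > 1e-9)
          stop("linearity in emissions violated")
      }
      env3 <- env; env3$options$z_water <- env$options$z_water * 1000
      res3 <- solve_steady_state(env3)
      if (max(abs(res3$table$concentration - res$table$concentration) /
                pmax(res$table$concentration, 1e-300)) > 1e-9)
        stop("normalization invariance violated")
      message("validate ", scenario, ": mass balance (residual ",
              format(resid, digits = 3),
              "), linearity, normalization invariance: OK")
    } else stop("unknown command: ", cmd, "\n", usage)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
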