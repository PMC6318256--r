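# One-at-a-time perturbation engine: apply a single structured change to a
# scenario, re-solve, and report percent changes with symbolic bins.

#' Define a scenario perturbation
#'
#' A single one-at-a-time change to an environment. Supported types:
#' \describe{
#'   \item{mixing}{multiply mixing-link rates (`value`); optionally restrict
#'     to links touching the compartments in `ids`.}
#'   \item{advection}{multiply all advective flow rates by `value` (a uniform
#'     water-velocity change).}
#'   \item{chemical}{modify `field` of the chemicals in `ids` by `action`
#'     (`"add"`, `"multiply"`, `"set"`) with `value`.}
#'   \item{reaction_disable}{remove all reactions of kind `ids` (e.g.
#'     `"photo"`, `"bio"`).}
#'   \item{reaction_rate}{multiply reaction rates by `value` (half-lives are
#'     divided); `ids = "tp_forming"` restricts to product-forming channels.}
#'   \item{photolysis_multiplier}{set compartment photolysis multipliers from
#'     the named vector `value`.}
#'   \item{emission_target}{move all emissions to compartment `value`.}
#'   \item{emission_scale}{multiply all emission molar rates by `value`.}
#'   \item{suspended_solids}{multiply water-compartment suspended-solids
#'     volume fractions by `value`.}
#'   \item{temperature}{`action` `"set"` or `"add"` `value` degrees C to the
#'     compartments in `ids` (default all).}
#'   \item{relink}{re-plumb advection: `value` is a data.frame with columns
#'     `source`, `old_target`, `new_target`.}
#' }
#'
#' @param type Perturbation type (see Details).
#' @param value Magnitude / replacement value.
#' @param ids Optional selector (compartments, chemicals or reaction kinds
#'   depending on `type`).
#' @param action `"multiply"`, `"add"` or `"set"` where applicable.
#' @param field Chemical field name for `type = "chemical"`.
#' @param label Human-readable label for reports.
#' @return Object of class `perturbation`.
#' @export
perturbation <- function(type, value = NULL, ids = NULL,
                         action = "multiply", field = NULL, label = NULL) {
  types <- c("mixing", "advection", "chemical", "reaction_disable",
             "reaction_rate", "photolysis_multiplier", "emission_target",
             "emission_scale", "suspended_solids", "temperature", "relink")
  if (!type %in% types) stop("unknown perturbation type: ", type)
  if (is.null(label)) label <- paste0(type, if (!is.null(field))
    paste0(":", field), if (is.numeric(value) && length(value) == 1)
      paste0(" ", action, " ", value))
  structure(list(type = type, value = value, ids = ids, action = action,
                 field = field, label = label), class = "perturbation")
}

apply_action <- function(old, action, value) {
  switch(action,
         multiply = old * value,
         add = old + value,
         set = value,
         stop("unknown action: ", action))
}

#' Apply a perturbation to an environment
#'
#' Returns a modified copy of the environment with the single change applied.
#' Flow-altering perturbations mark the copy as re-plumbed, which relaxes the
#' strict hydraulic-continuity invariant (a fixed effluent water flow cannot
#' stay balanced under a uniform flow scaling).
#'
#' @param env An [environment_spec()].
#' @param p A [perturbation()].
#' @return The perturbed environment.
#' @export
apply_perturbation <- function(env, p) {
  stopifnot(inherits(p, "perturbation"))
  switch(p$type,
    mixing = {
      sel <- env$links$kind == "mixing"
      if (!is.null(p$ids))
        sel <- sel & (env$links$source %in% p$ids | env$links$target %in% p$ids)
      if (!any(sel)) stop("no mixing links match: ",
                          paste(p$ids, collapse = ", "))
      env$links$rate[sel] <- apply_action(env$links$rate[sel], p$action, p$value)
    },
    advection = {
      sel <- env$links$kind == "advection"
      env$links$rate[sel] <- apply_action(env$links$rate[sel], p$action, p$value)
      env$validate_continuity <- FALSE
    },
    chemical = {
      if (is.null(p$field)) stop("chemical perturbation needs a field")
      for (id in p$ids) {
        if (!id %in% names(env$chemicals)) stop("unknown chemical: ", id)
        if (!p$field %in% names(env$chemicals[[id]]))
          stop("unknown chemical field: ", p$field)
        env$chemicals[[id]][[p$field]] <-
          apply_action(env$chemicals[[id]][[p$field]], p$action, p$value)
      }
    },
    reaction_disable = {
      if (!all(p$ids %in% env$reactions$kind))
        stop("no reactions of kind: ",
             paste(setdiff(p$ids, env$reactions$kind), collapse = ", "))
      env$reactions <- env$reactions[!env$reactions$kind %in% p$ids, ,
                                     drop = FALSE]
    },
    reaction_rate = {
      sel <- rep(TRUE, nrow(env$reactions))
      if (identical(p$ids, "tp_forming")) sel <- env$reactions$product != "other"
      else if (!is.null(p$ids)) sel <- env$reactions$kind %in% p$ids
      # rate multiplier = half-life divisor
      env$reactions$half_life_h[sel] <- env$reactions$half_life_h[sel] / p$value
    },
    photolysis_multiplier = {
      ids <- names(p$value)
      if (!all(ids %in% env$compartments$id))
        stop("unknown compartment in photolysis_multiplier: ",
             paste(setdiff(ids, env$compartments$id), collapse = ", "))
      env$compartments$photolysis_multiplier[
        match(ids, env$compartments$id)] <- as.numeric(p$value)
    },
    emission_target = {
      if (!p$value %in% env$compartments$id)
        stop("unknown emission target: ", p$value)
      env$emissions$compartment <- p$value
      env$validate_continuity <- FALSE
    },
    emission_scale = {
      env$emissions$mol_h <- env$emissions$mol_h * p$value
    },
    suspended_solids = {
      sel <- env$compartments$medium == "surface_water"
      env$compartments$ss_volume_fraction[sel] <-
        env$compartments$ss_volume_fraction[sel] * p$value
      # the solids deposition flux is carried by the suspended load, so it
      # scales with it
      dep <- env$links$kind == "sediment_exchange"
      env$links$u_dep[dep] <- env$links$u_dep[dep] * p$value
    },
    temperature = {
      ids <- if (is.null(p$ids)) env$compartments$id else p$ids
      if (!all(ids %in% env$compartments$id))
        stop("unknown compartment: ",
             paste(setdiff(ids, env$compartments$id), collapse = ", "))
      sel <- env$compartments$id %in% ids
      env$compartments$temperature[sel] <-
        apply_action(env$compartments$temperature[sel],
                     if (p$action == "multiply") "set" else p$action, p$value)
    },
    relink = {
      rl <- p$value
      for (r in seq_len(nrow(rl))) {
        sel <- env$links$kind == "advection" &
          env$links$source == rl$source[r] &
          env$links$target == rl$old_target[r]
        if (!any(sel)) stop("no advection link ", rl$source[r], " -> ",
                            rl$old_target[r])
        env$links$target[sel] <- rl$new_target[r]
      }
      env$validate_continuity <- FALSE
    })
  env
}

#' Symbolic bin for a percent change
#'
#' Bins follow the reporting legend: `+` 1-10%, `++` 10-100%, `+++`
#' 100-1000%, `++++` above 1000%; `-` -1 to -10%, `--` -10 to -50%, `---`
#' -50 to -100%; `0` for changes below 1% in magnitude.
#'
#' @param pct Percent change(s).
#' @return Character vector of symbols.
#' @export
bin_percent_change <- function(pct) {
  vapply(pct, function(x) {
    if (!is.finite(x)) return(NA_character_)
    a <- abs(x)
    if (a < 1) return("0")
    if (x > 0) {
      if (a < 10) "+" else if (a < 100) "++" else if (a < 1000) "+++"
      else "++++"
    } else {
      if (a < 10) "-" else if (a < 50) "--" else "---"
    }
  }, character(1))
}

#' Run a one-at-a-time sensitivity survey
#'
#' Solves the baseline scenario and each perturbed variant, and reports the
#' percent change of every compartment-chemical concentration with its
#' symbolic bin. Failures of individual perturbations are isolated and
#' collected rather than aborting the survey.
#'
#' @param env An [environment_spec()].
#' @param perturbations List of [perturbation()] objects.
#' @return Object of class `sensitivity_report`: `table` (perturbation,
#'   compartment, chemical, baseline, perturbed, pct_change, symbol),
#'   `baseline` (the baseline `fate_result`), `failures` (named list of error
#'   messages).
#' @export
run_sensitivity <- function(env, perturbations) {
  base <- solve_steady_state(env)
  key <- paste(base$table$compartment, base$table$chemical, sep = "|")
  rows <- list(); failures <- list()
  for (p in perturbations) {
    res <- tryCatch(solve_steady_state(apply_perturbation(env, p)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[p$label]] <- conditionMessage(res)
      next
    }
    # chain regrouping (e.g. after disabling a pathway) may reorder rows
    perturbed <- res$table$concentration[
      match(key, paste(res$table$compartment, res$table$chemical, sep = "|"))]
    pct <- ifelse(base$table$concentration > 0,
                  100 * (perturbed - base$table$concentration) /
                    base$table$concentration,
                  ifelse(perturbed > 0, Inf, 0))
    rows[[length(rows) + 1]] <- data.frame(
      perturbation = p$label, compartment = base$table$compartment,
      chemical = base$table$chemical,
      baseline = base$table$concentration,
      perturbed = perturbed,
      pct_change = pct, symbol = bin_percent_change(pct),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), baseline = base,
                 failures = failures),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  perts <- unique(x$table$perturbation)
  cat("<sensitivity_report>", length(perts), "perturbation(s)\n")
  for (p in perts) {
    tb <- x$table[x$table$perturbation == p, ]
    big <- tb[order(-abs(tb$pct_change)), ][1:min(3, nrow(tb)), ]
    cat(" *", p, "- largest effects:\n")
    for (r in seq_len(nrow(big)))
      cat(sprintf("     %s/%s: %+.1f%% (%s)\n", big$compartment[r],
                  big$chemical[r], big$pct_change[r], big$symbol[r]))
  }
  if (length(x$failures))
    cat("failed:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
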