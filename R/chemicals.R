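#' Chemical property specification
#'
#' Bundles the physicochemical properties the fate engine needs for one
#' chemical: molar mass, water solubility, log Kow, pKa, its dissociation
#' class, and the chemical-specific Koc/Kow proportionality. Solubility and
#' log Kow can be given either as neutral-species values or as pH-7 effective
#' values covering neutral and dissociated forms together (`property_mode`);
#' the latter is how the packaged property tables are expressed.
#'
#' @param id Short chemical identifier, e.g. `"IBU"`.
#' @param molecular_weight Molar mass, g/mol. Must be positive.
#' @param water_solubility Water solubility, g/l, at the reference conditions
#'   implied by `property_mode`.
#' @param log_kow log10 octanol-water partition coefficient at the reference
#'   conditions implied by `property_mode`.
#' @param pka Acid dissociation constant (for bases: of the conjugate acid).
#'   Ignored when `dissociation_class = "neutral"`.
#' @param dissociation_class One of `"acid"`, `"base"`, `"neutral"`.
#' @param koc_kow_ratio Chemical-specific Koc/Kow proportionality; defaults to
#'   the conventional 0.41 when `NULL`.
#' @param property_mode `"at_ph7"` (solubility/log Kow are pH-7 effective
#'   values for neutral + ionized species together) or `"neutral_species"`.
#' @param sol_temp_coef,kow_temp_coef Optional linear-in-temperature
#'   log10-scale coefficients (per degree C) applied around the 25 degree C
#'   reference; default `0` (off).
#' @param inherited Character vector naming fields whose values were inherited
#'   from a parent compound rather than measured/estimated for this chemical
#'   (metadata only).
#' @return An object of class `chemical_spec`.
#' @export
chemical_spec <- function(id, molecular_weight, water_solubility, log_kow,
                          pka = NA_real_,
                          dissociation_class = c("acid", "base", "neutral"),
                          koc_kow_ratio = NULL,
                          property_mode = c("at_ph7", "neutral_species"),
                          sol_temp_coef = 0, kow_temp_coef = 0,
                          inherited = character()) {
  dissociation_class <- match.arg(dissociation_class)
  property_mode <- match.arg(property_mode)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be > 0 for ", id)
  if (!is.numeric(water_solubility) || water_solubility <= 0)
    stop("water_solubility must be > 0 for ", id)
  if (is.null(koc_kow_ratio)) koc_kow_ratio <- 0.41
  if (koc_kow_ratio <= 0) stop("koc_kow_ratio must be > 0 for ", id)
  if (dissociation_class != "neutral" && !is.finite(pka))
    stop("pka required for non-neutral chemical ", id)
  structure(list(
    id = id,
    molecular_weight = molecular_weight,
    water_solubility = water_solubility,
    log_kow = log_kow,
    pka = if (dissociation_class == "neutral") NA_real_ else pka,
    dissociation_class = dissociation_class,
    koc_kow_ratio = koc_kow_ratio,
    property_mode = property_mode,
    sol_temp_coef = sol_temp_coef,
    kow_temp_coef = kow_temp_coef,
    inherited = inherited
  ), class = "chemical_spec")
}

#' @export
print.chemical_spec <- function(x, ...) {
  cat(sprintf("<chemical_spec> %s (MW %.2f g/mol, %s)\n", x$id,
              x$molecular_weight, x$dissociation_class))
  cat(sprintf("  S = %g g/l, logKow = %g (%s), pKa = %s, Koc/Kow = %g\n",
              x$water_solubility, x$log_kow, x$property_mode,
              ifelse(is.na(x$pka), "-", format(x$pka)), x$koc_kow_ratio))
  if (length(x$inherited))
    cat("  inherited from parent:", paste(x$inherited, collapse = ", "), "\n")
  invisible(x)
}

#' Ambient property context
#'
#' Temperature and pH of the medium for which effective chemical properties
#' are evaluated.
#'
#' @param temperature Degrees C, in [-5, 40].
#' @param ph pH, in (0, 14).
#' @return An object of class `property_context`.
#' @export
property_context <- function(temperature = 25, ph = 7) {
  if (!is.numeric(temperature) || temperature < -5 || temperature > 40)
    stop("temperature out of range [-5, 40]: ", temperature)
  if (!is.numeric(ph) || ph <= 0 || ph >= 14)
    stop("ph out of range (0, 14): ", ph)
  structure(list(temperature = temperature, ph = ph),
            class = "property_context")
}

# Reference conditions of the packaged property tables.
REF_TEMPERATURE <- 25
REF_PH <- 7

# Ionization multiplier 1 + 10^(ph - pka) (acid) capped to avoid overflow at
# extreme ph - pka; the cap corresponds to a fully-ionized factor of 1e6.
ION_MULT_CAP <- 1e6

#' Ionized fraction of an acid or base
#'
#' Henderson-Hasselbalch dissociated fraction. For acids
#' `1 / (1 + 10^(pka - ph))`, for bases `1 / (1 + 10^(ph - pka))`, and 0 for
#' neutral chemicals.
#'
#' @param pka Dissociation constant.
#' @param ph Ambient pH.
#' @param cls Dissociation class: `"acid"`, `"base"` or `"neutral"`.
#' @return Fraction in [0, 1].
#' @export
ionized_fraction <- function(pka, ph, cls = c("acid", "base", "neutral")) {
  cls <- match.arg(cls)
  switch(cls,
         acid = 1 / (1 + 10^(pka - ph)),
         base = 1 / (1 + 10^(ph - pka)),
         neutral = 0)
}

# Multiplier relating neutral-species solubility to total (neutral + ionized)
# effective solubility at a given pH; >= 1, capped with a warning.
ionization_multiplier <- function(spec, ph) {
  expo <- switch(spec$dissociation_class,
                 acid = ph - spec$pka,
                 base = spec$pka - ph,
                 neutral = -Inf)
  mult <- 1 + 10^expo
  if (mult > ION_MULT_CAP) {
    warning("ionization multiplier capped at 1e6 for ", spec$id,
            " (|pH - pKa| extreme)")
    mult <- ION_MULT_CAP
  }
  mult
}

# Neutral-species solubility at 25 C implied by the spec's tabulated value.
neutral_solubility <- function(spec) {
  if (spec$property_mode == "neutral_species") return(spec$water_solubility)
  spec$water_solubility / ionization_multiplier(spec, REF_PH)
}

#' Effective (total-species) water solubility
#'
#' Corrects the tabulated solubility for ionization at the ambient pH: the
#' neutral-species solubility is multiplied by `1 + 10^(ph - pka)` for acids
#' (symmetrically for bases). Tables stored in pH-7 mode are first inverted to
#' the neutral-species value, so at pH 7 the tabulated value is returned
#' unchanged. An optional linear-in-T log-scale temperature coefficient is
#' applied multiplicatively around 25 degrees C (off by default).
#'
#' @param spec A [chemical_spec()].
#' @param ctx A [property_context()].
#' @return Effective solubility, g/l.
#' @export
effective_solubility <- function(spec, ctx = property_context()) {
  s <- neutral_solubility(spec) * ionization_multiplier(spec, ctx$ph)
  if (spec$sol_temp_coef != 0)
    s <- s * 10^(spec$sol_temp_coef * (ctx$temperature - REF_TEMPERATURE))
  s
}

#' Effective log Kow at ambient pH
#'
#' Octanol solubility is treated as pH-invariant: `S_oct = Kow(pH7) * S(pH7)`.
#' The effective Kow at another pH is `S_oct / S_eff(pH)`, so ionization
#' lowers the apparent lipophilicity of an acid as pH rises. At the tabulated
#' reference pH the tabulated value is returned unchanged.
#'
#' @inheritParams effective_solubility
#' @return log10 Kow (dimensionless).
#' @export
effective_log_kow <- function(spec, ctx = property_context()) {
  # octanol solubility from the tabulated pair (pH-invariant by assumption)
  s_ref <- if (spec$property_mode == "at_ph7")
    spec$water_solubility else neutral_solubility(spec)
  s_oct <- 10^spec$log_kow * s_ref
  if (spec$kow_temp_coef != 0)
    s_oct <- s_oct * 10^(spec$kow_temp_coef * (ctx$temperature - REF_TEMPERATURE))
  log10(s_oct / effective_solubility(spec, ctx))
}

#' Organic-carbon partition coefficient
#'
#' `Koc = (Koc/Kow ratio) * 10^effective_log_kow(ctx)`, l/kg organic carbon.
#' The ratio defaults to the conventional 0.41 when the spec does not carry a
#' chemical-specific value.
#'
#' @inheritParams effective_solubility
#' @return Koc, l per kg organic carbon.
#' @export
koc <- function(spec, ctx = property_context()) {
  spec$koc_kow_ratio * 10^effective_log_kow(spec, ctx)
}

#' Packaged chemical property table
#'
#' Loads the packaged property records for the three parent pharmaceuticals
#' (ibuprofen IBU, diclofenac DCF, carbamazepine CBZ) and their selected
#' transformation products, as a named list of [chemical_spec()] objects.
#' Values are pH-7 effective solubilities and log Kow (25 degrees C);
#' parenthesised table entries inherited from the parent compound are flagged
#' in the `inherited` metadata field.
#'
#' @param path Optional path to an alternative property CSV with the same
#'   columns as the packaged `chemical_properties.csv`.
#' @return Named list of `chemical_spec` objects.
#' @export
default_chemicals <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chemical_properties.csv",
                        package = "lakefate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    chemical_spec(
      id = r$id,
      molecular_weight = r$molecular_weight,
      water_solubility = r$water_solubility,
      log_kow = r$log_kow,
      pka = r$pka,
      dissociation_class = r$dissociation_class,
      koc_kow_ratio = r$koc_kow_ratio,
      property_mode = "at_ph7",
      inherited = if (nzchar(r$inherited))
        strsplit(r$inherited, ";", fixed = TRUE)[[1]] else character()
    )
  })
  names(specs) <- tab$id
  specs
}

#' Derive a conjugate pseudo-chemical from a parent
#'
#' Builds a pseudo-chemical (e.g. an ibuprofen conjugate pool) that shares all
#' partitioning properties with its parent; its only distinct behaviour is a
#' deconjugation reaction back to the parent, registered separately via the
#' reaction table.
#'
#' @param parent A [chemical_spec()].
#' @param id Identifier for the pseudo-chemical (default `"<parent>-CONJ"`).
#' @return A `chemical_spec` cloned from the parent.
#' @export
conjugate_spec <- function(parent, id = paste0(parent$id, "-CONJ")) {
  out <- parent
  out$id <- id
  out$inherited <- setdiff(names(out), c("id", "inherited"))
  out
}
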