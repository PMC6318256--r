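# Programmatic toy fixtures used across the suite.

make_chem <- function(id = "PAR", mw = 200, sol = 1, logkow = 2, pka = 5,
                      cls = "acid", ratio = 0.41) {
  chemical_spec(id, mw, sol, logkow, pka = pka, dissociation_class = cls,
                koc_kow_ratio = ratio, property_mode = "at_ph7")
}

no_reactions <- function() {
  reaction_table(character(), character(), character(), numeric())
}

# One well-mixed water box, one chemical, advective throughput, no reactions.
toy_one_box <- function(E = 0.01, G = 500, V = 1e4, temperature = 25) {
  ch <- list(PAR = make_chem())
  comps <- compartment_spec("W", "surface_water", volume = V,
                           temperature = temperature, ph = 7,
                           ss_volume_fraction = 3.6e-5,
                           photolysis_multiplier = 1)
  links <- rbind(flow_link("advection", "inflow", "W", rate = G),
                 flow_link("advection", "W", "outflow", rate = G))
  emis <- emission_spec("W", "PAR", mol_h = E)
  environment_spec(comps, links, emis, ch, no_reactions())
}

# One box with a parent -> product photo pair (full sunlight, 25 C so no
# temperature correction confounds closed forms).
toy_parent_tp <- function(E = 0.01, G = 500, V = 1e4,
                          t_par_form = 100, t_par_other = 50, t_tp = 30) {
  ch <- list(PAR = make_chem("PAR"),
             TP = make_chem("TP", mw = 180, logkow = 1))
  reacts <- reaction_table(c("PAR", "PAR", "TP"), c("TP", "other", "other"),
                           rep("photo", 3), c(t_par_form, t_par_other, t_tp))
  comps <- compartment_spec("W", "surface_water", volume = V,
                           temperature = 25, ph = 7,
                           ss_volume_fraction = 3.6e-5,
                           photolysis_multiplier = 1)
  links <- rbind(flow_link("advection", "inflow", "W", rate = G),
                 flow_link("advection", "W", "outflow", rate = G))
  emis <- emission_spec("W", "PAR", mol_h = E)
  environment_spec(comps, links, emis, ch, reacts)
}

# Two stacked water boxes over a sediment slab; parent+product chain with
# photolysis in the surface box and biotransformation in the sediment.
toy_three_box <- function(E = 0.01) {
  ch <- list(PAR = make_chem("PAR"),
             TP = make_chem("TP", mw = 180, logkow = 1))
  reacts <- reaction_table(c("PAR", "PAR", "PAR", "TP"),
                           c("TP", "other", "TP", "other"),
                           c("photo", "photo", "bio", "bio"),
                           c(100, 50, 40, 10))
  comps <- rbind(
    compartment_spec("W1", "surface_water", volume = 5e3, temperature = 25,
                     ph = 7, ss_volume_fraction = 3.6e-5,
                     photolysis_multiplier = 1),
    compartment_spec("W2", "surface_water", volume = 2e4, temperature = 25,
                     ph = 7, ss_volume_fraction = 3.6e-5,
                     photolysis_multiplier = 0),
    compartment_spec("SED", "bottom_sediment", volume = 20, temperature = 25,
                     ph = 7, oc_fraction = 0.06, porosity = 0.8))
  links <- rbind(flow_link("advection", "inflow", "W1", rate = 400),
                 flow_link("advection", "W1", "outflow", rate = 400),
                 flow_link("mixing", "W1", "W2", rate = 800),
                 flow_link("sediment_exchange", "W2", "SED", area = 1000))
  emis <- emission_spec("W1", "PAR", mol_h = E)
  environment_spec(comps, links, emis, ch, reacts)
}

# Cached expensive baseline solves, shared across test files.
ns_env_cached <- local({
  env <- NULL
  function() {
    if (is.null(env)) env <<- build_paijanne_ns()
    env
  }
})

ns_result_cached <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- solve_steady_state(ns_env_cached())
    res
  }
})
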