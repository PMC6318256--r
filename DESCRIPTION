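Package: lakefate
Title: Steady-State Multimedia Fugacity Modelling of Pharmaceuticals and
    Their Transformation Products in a Stratified Lake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Level III (steady-state, flow-connected) multimedia fugacity
    model for ionizable organic chemicals in stratified lake environments.
    Compartment-by-chemical linear mass-balance systems are assembled per
    reaction chain, so first-order transformation products (photolysis,
    biotransformation, deconjugation) are modelled alongside their parent
    compounds. Includes pH (Henderson-Hasselbalch) and temperature corrections
    of chemical properties, depth-banded photolysis attenuation, packaged
    scenarios for a wastewater effluent plume in a thermally stratified lake
    with downstream plug-flow transport chains, a one-at-a-time sensitivity
    engine, and a dynamic integrator used as a verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
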