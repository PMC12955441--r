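# Shared fixtures for the simulation-driven tests.

default_params <- function(...) simulation_params(...)

# A well with both targets at moderate occupancy, default artefacts
# (competition kappa = 0.5, crosstalk alpha = 0.05).
duplex_well <- function(seed = 42,
                        fam = 468.6, hex = 100,
                        params = simulation_params()) {
  simulate_reaction(params, true_concentrations(fam, hex), seed = seed)
}

# copies/reaction implied by a concentration in copies/µL
copies_rxn <- function(conc_per_ul, vr = 20) conc_per_ul * vr

# lambda implied by a concentration for given droplet volume (nL)
lambda_of <- function(conc_per_ul, vd_nl = 0.85) conc_per_ul * vd_nl * 1e-3
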