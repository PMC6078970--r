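# Shared fixtures: the reference composition of the assembly experiments
# (subunits at 1 g/L = 24.6 uM, mass ratio 6, molar ratio 150) and a
# matching parameter set with critical concentration 13.6 uM.

ref_comp <- function(rho = 6) mixture_composition(c_S = 24.6e-6, rho = rho)

ref_params <- function(k_plus = 2.2e8, K_inv = 13.6e-6, n_max = 200L)
  kinetic_parameters(k_plus, k_plus * K_inv, n_max = n_max)

# truncated geometric occupancy distribution with ratio r, as a
# complex_distribution (independent construction used as an oracle)
geometric_distribution <- function(r, n_max, c_G = 1, X_S = 1) {
  w <- r^(0:n_max)
  complex_distribution(c_G * w / sum(w), X_S = X_S)
}
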