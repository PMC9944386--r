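# Shared fixtures: parameter bundles spanning every analytic case, built
# around a 150 mg dose and a 1/3 per-hour reference rate.

ref_k <- 1 / 3
ref_a0 <- 150

# Dimensionally consistent k_a_max for arbitrary exponents: k_a_max has
# units amount^(1 + gamma2 - gamma1) / time, carried by a50.
scaled_kamax <- function(a50, gamma1, gamma2, k = ref_k)
  k * a50^(1 + gamma2 - gamma1)

case_b_bundle <- function(gamma2, ratio, a0 = ref_a0) {
  a50 <- ratio * a0
  absorption_params(scaled_kamax(a50, 1, gamma2), a50, 1, gamma2, a0)
}

case_d_bundle <- function(gamma1, ratio, a0 = ref_a0) {
  a50 <- ratio * a0
  absorption_params(scaled_kamax(a50, gamma1, gamma1 - 1), a50,
                    gamma1, gamma1 - 1, a0)
}

# The verification grid used by the oracle-equivalence checks.
oracle_grid <- function() {
  ratios <- c(0.1, 0.5, 2, 10)
  bundles <- list()
  for (g2 in c(0.25, 0.5, 1, 2, 4))
    for (r in ratios)
      bundles[[length(bundles) + 1]] <- case_b_bundle(g2, r)
  for (g1 in c(1.5, 2, 3))
    for (r in ratios)
      bundles[[length(bundles) + 1]] <- case_d_bundle(g1, r)
  bundles[[length(bundles) + 1]] <-
    absorption_params(2 * ref_k, 75, 1, 0, ref_a0)          # case C
  bundles[[length(bundles) + 1]] <-
    absorption_params(scaled_kamax(75, 2, 0), 75, 2, 0, ref_a0)  # power law
  bundles
}

mm_fig1 <- function() {
  a50 <- 10 * ref_a0
  absorption_params(a50 * ref_k, a50, 1, 1, ref_a0)
}

rel_err <- function(x, ref, floor = 0)
  abs(x - ref) / pmax(abs(ref), floor)
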