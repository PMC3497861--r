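# Shared fixtures.  The full factorial study grid is expensive (a few
# minutes), so it is computed once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

study_grid_cached <- function() {
  if (is.null(.fixture_env$grid))
    .fixture_env$grid <- run_study_grid(n_breaths = 6, dt = 1e-3,
                                        keep_iterations = TRUE)
  .fixture_env$grid
}

# Printed equivalent-resistance table (cm H2O s/l): resistor catalogue k,
# reference flows, and the published two-significant-figure cells.
printed_resistance_table <- function() {
  data.frame(
    resistor = rep(c("Rp5", "Rp20", "Rp50"), each = 2),
    k = rep(c(3.3, 21.5, 132.9), each = 2),
    flow_lpm = rep(c(20, 60), 3),
    air = c(0.9, 2.7, 5.8, 17.5, 36.1, 108.4),
    heo2 = c(0.3, 0.9, 2.0, 6.1, 12.7, 38.0)
  )
}

# A standard asymmetric test system: Rp5 left, arbitrary right resistor.
make_test_system <- function(k_right = 132.9, compliance = 0.05,
                             gas = heliox(), k_fs = 1.2,
                             circuit = circuit_loss_model(),
                             volume_left = 0, volume_right = 0,
                             allow_pendelluft = TRUE) {
  A <- default_resistor_area()
  lung_system(
    left = lung_chamber(compliance, parabolic_resistor(3.3, A),
                        k_fs = k_fs, volume = volume_left),
    right = lung_chamber(compliance, parabolic_resistor(k_right, A),
                         k_fs = k_fs, volume = volume_right),
    gas = gas, circuit = circuit, area = A,
    allow_pendelluft = allow_pendelluft)
}
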