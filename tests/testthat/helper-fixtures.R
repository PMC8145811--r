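# Shared fixtures, all built in code.

fixture_q <- function(n = 200, q_min = 0.005, q_max = 0.4) {
  seq(q_min, q_max, length.out = n)
}

# noise-free absolute-scale complex curve for a preset row
fixture_complex_curve <- function(preset = "sds10.5", q = fixture_q(),
                                  sigma_rel = 0.01) {
  p <- as.list(complex_preset(preset))
  I <- complex_intensity(q, p)
  saxs_curve(q, I, sigma = sigma_rel * I, label = preset)
}

# simple homogeneous sphere curve: I = (k Phi(qR))^2
fixture_sphere_curve <- function(R = 30, q = seq(0.001, 0.8, length.out = 600),
                                 k = 1e-10, sigma_rel = 0.01) {
  I <- (k * sphere_amplitude(q * R))^2 * 1e16
  saxs_curve(q, I, sigma = sigma_rel * I, label = "sphere")
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(object - expected) / abs(expected)),
                              tol))
}
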