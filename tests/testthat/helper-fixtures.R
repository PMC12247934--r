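# shared fixtures: everything is generated in code at test time

compliant <- vessel_preset("compliant")
stiff <- vessel_preset("stiff")

# the standard physiological pulsatile drive (80/120 mmHg)
physio_drive <- function(beat_rate = 65, duration = 30, sample_rate = 50) {
  generate_pulsatile_pressure(
    pulse_spec(80, 120, beat_rate, duration, sample_rate))
}

# central finite-difference oracle for lambda_theta * dW/dlambda_theta
fd_circ_stress <- function(params, lt, lz = 1, h = 1e-5) {
  lt * (strain_energy(params, lt + h, lz) -
          strain_energy(params, lt - h, lz)) / (2 * h)
}

# brute-force count of interior local maxima (plateaus counted once)
count_maxima <- function(x) {
  n <- length(x)
  cnt <- 0
  i <- 2
  while (i < n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) cnt <- cnt + 1
      i <- j + 1
    } else i <- i + 1
  }
  cnt
}
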