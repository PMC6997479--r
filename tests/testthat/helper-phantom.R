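# shared fixtures built in code

toy_schedule <- function(n = 3, dt = 1, modality = "mru") {
  acquisition_schedule(seq(0, by = dt, length.out = n), rep(dt, n),
                       modality = modality)
}

toy_tac <- function(values, dt = 1, modality = "mru", label = "") {
  n <- length(values)
  tac(seq(dt / 2, by = dt, length.out = n), rep(dt, n), values,
      label = label, modality = modality)
}

# standard aortic input on the default fMRU schedule
default_aif <- function(schedule = mru_schedule()) aortic_input(schedule)

add_curve_noise <- function(curve, sd_frac, seed) {
  set.seed(seed)
  v <- curve$value + stats::rnorm(length(curve$value),
                                  0, sd_frac * max(curve$value))
  tac(curve$time, curve$duration, pmax(v, 0), label = curve$label,
      modality = curve$modality)
}

# published drainage-concordance counts shipped with the package
concordance_table <- function() {
  read_contingency_table(system.file("extdata",
                                     "drainage_concordance_counts.csv",
                                     package = "renogram"))
}
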