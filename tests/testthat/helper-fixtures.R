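# Shared fixtures for the test suite: a season history data frame and a
# parameter builder with overridable fields.

params_with <- function(...) {
  p <- default_parameters()
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  validate_parameters(p)
  p
}

season_history <- function(months, E = 0, J = 0, N1 = 0, N2 = 0, N3 = 0) {
  n <- length(months)
  data.frame(month = months,
             E = rep_len(E, n), J = rep_len(J, n),
             N1 = rep_len(N1, n), N2 = rep_len(N2, n), N3 = rep_len(N3, n))
}
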