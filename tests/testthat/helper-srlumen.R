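# Shared fixtures: coarse configurations that keep unit tests fast while
# exercising the same code paths as the production resolutions.

coarse_config <- function(duration = 0.02, ..., spacing = 5e-8,
                          n_output_points = 41L) {
  simulation_config(duration = duration, n_output_points = n_output_points,
                    spacing = spacing, ...)
}

default_params <- sr_parameters()
default_geom <- sr_geometry()

# Independent mass-action oracle: bracketing root of
# (T - b)(Cq - b) - Kd b = 0 on [0, min(T, Cq)].
bound_by_bracketing <- function(ca_total, casq_total, Kd) {
  if (ca_total == 0 || casq_total == 0) return(0)
  g <- function(b) (ca_total - b) * (casq_total - b) - Kd * b
  upper <- min(ca_total, casq_total)
  stats::uniroot(g, c(0, upper), tol = 1e-14 * max(1, upper))$root
}
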