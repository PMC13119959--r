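# Shared fixtures and small oracles. The model is deterministic; property
# tests draw random cases under fixed seeds.

options(biobattery.verbosity = "quiet")

baseline_mp <- function(...) microbial_params(...)
baseline_ep <- function(...) electro_params(...)
baseline_init <- function(...) anolyte_state(...)

# conversion factor j [A m^-2] per unit volumetric flux [mmol L^-1 h^-1]
j_factor <- function(ep) ep$n_e * ep$F_C / (ep$A * 1000 * 3600)

# trapezoidal integral oracle
trapz <- function(x, y) sum(0.5 * diff(x) * (y[-1] + y[-length(y)]))

# mixed relative/absolute deviation: relative where the reference is of
# appreciable size, absolute (scaled to `scale`) where it is near zero
rel_dev <- function(a, b, scale) abs(a - b) / pmax(abs(b), scale)

# The default design sweep is the most expensive computation in the suite;
# compute it once and reuse across test files (tests run in one session).
.sweep_cache <- new.env(parent = emptyenv())
default_sweep <- function() {
  if (is.null(.sweep_cache$sw))
    .sweep_cache$sw <- design_sweep(sweep_spec(), dt = 0.01)
  .sweep_cache$sw
}

baseline_batch <- function() {
  if (is.null(.sweep_cache$batch))
    .sweep_cache$batch <- simulate_batch(anolyte_state(), microbial_params(),
                                         electro_params(),
                                         termination_spec(t_max = 200),
                                         dt = 0.01)
  .sweep_cache$batch
}
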