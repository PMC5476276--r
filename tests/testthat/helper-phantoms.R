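# Shared fixtures: small phantoms generated in code, cached per test run.

# planar stack: no pit, no bowing, no wobble, no speckle
planar_spec <- function(seed = 1L, ...) {
  phantom_spec(speckle_shape = Inf, curvature_um = 0, thickness_wobble = 0,
               fovea = list(offset_mm = c(0, 0), pit_depth_um = 0,
                            pit_radius_mm = 0.6),
               seed = seed, ...)
}

# pit + bowing but laterally homogeneous layers, noise-free
pit_spec <- function(seed = 1L, ...) {
  phantom_spec(speckle_shape = Inf, thickness_wobble = 0, seed = seed, ...)
}

.cache <- new.env(parent = emptyenv())

cached_volume <- function(key, spec_fun) {
  if (is.null(.cache[[key]])) .cache[[key]] <- generate_volume(spec_fun())
  .cache[[key]]
}

planar_phantom <- function() cached_volume("planar", planar_spec)
pit_phantom <- function() cached_volume("pit", pit_spec)
default_phantom <- function() cached_volume("default",
                                            function() phantom_spec(seed = 7L))

# brute-force Mann-Whitney U of x against y (ties count half)
brute_force_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
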