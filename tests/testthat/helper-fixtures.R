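# shared fixtures; expensive pipeline runs are computed once per session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default-conditions phantom pipeline (noisy)
default_pipeline <- function() {
  cached("default_pipeline", run_phantom_pipeline(phantom_spec()))
}

# noiseless, jitter-free round-trip pipeline
noiseless_pipeline <- function() {
  cached("noiseless_pipeline",
         run_phantom_pipeline(phantom_spec(noise_sd = 0,
                                           chi_params = list(jitter_sd = 0))))
}

# small geometry for cheap unit tests
unit_geometry <- function(n = 16, voxel = c(1, 1, 1)) {
  vol_geometry(rep(n, 3), voxel)
}

# uniform chi sphere and its forward field on a 32^3 grid
sphere_fixture <- function(radius = 6, dchi = 0.1) {
  cached(sprintf("sphere_%s_%s", radius, dchi), {
    g <- unit_geometry(32)
    co <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
    rad <- sqrt((co$x - 16.5)^2 + (co$y - 16.5)^2 + (co$z - 16.5)^2)
    inside <- array(rad <= radius, dim = c(32, 32, 32))
    chi <- array(0, dim = c(32, 32, 32))
    chi[inside] <- dchi
    list(geometry = g, chi = chi, inside = inside,
         field = forward_dipole_field(chi, g))
  })
}
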