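# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# full-size phantom at the study voxel geometries
default_phantom <- function() {
  fixture("default_phantom", function() generate_phantom(phantom_spec()))
}

default_mask <- function() {
  fixture("default_mask", function() build_body_mask(default_phantom()$kvct))
}

# phantom with a 5 mm nonrigid component, for warp-recovery tests
warp_phantom <- function() {
  fixture("warp_phantom", function()
    generate_phantom(phantom_spec(deform_max = 5)))
}

warp_mask <- function() {
  fixture("warp_mask", function() build_body_mask(warp_phantom()$kvct))
}

warp_fraction <- function() {
  fixture("warp_fraction", function() generate_fraction(warp_phantom(), 1))
}

# small phantom for cheap I/O and unit tests
small_phantom <- function() {
  fixture("small_phantom", function()
    generate_phantom(phantom_spec(kvct_dim = c(40, 40, 10),
                                  mvct_dim = c(96, 96, 6))))
}

# random convex polygon (points on a noisy circle, hull-ordered)
random_convex_polygon <- function(n = 12, center = c(0, 0), radius = 10) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- radius * (0.7 + 0.3 * runif(n))
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  pts[grDevices::chull(pts), , drop = FALSE]
}

square_polygon <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}
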