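# Shared small fixtures, built once per test run.

# random non-degenerate simplex (vertices i.i.d. uniform, retried if flat)
random_simplex <- function(d) {
  repeat {
    x <- matrix(stats::runif((d + 1) * d, -1, 1), d + 1, d)
    v <- abs(det(t(x[-1, , drop = FALSE]) - x[1, ]))
    if (v > 1e-3) return(x)
  }
}

random_rotation <- function(d) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# coarse aortic root, shared across test files (generation is the slow part)
coarse_root <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_aortic_root(root_params(mesh_size = 5))
    cache
  }
})

# small two-leaflet channel fixture
small_channel <- function(mesh_size = 0.0025) {
  generate_2d_valve_channel(channel_length = 0.06, channel_height = 0.02,
                            leaflet_length = 0.0085, leaflet_thickness = 0.0022,
                            mesh_size = mesh_size, n_leaflets = 2L,
                            leaflet_x = 0.02)
}
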