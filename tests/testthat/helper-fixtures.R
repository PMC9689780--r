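# Shared tiny fixtures, built once per test run.

tiny_table <- function(n = 3) subset_tissue_table(default_tissue_table(), n)

# small sphere contrast volume on an n^3 grid
sphere_volumes <- function(n = 10, radius = 0.05, eps_in = 2, sigma_in = 0.1,
                           side = 0.24) {
  g <- braintomo:::voxel_grid(n, side)
  rr <- sqrt(rowSums(g^2))
  eps <- array(1, rep(n, 3)); sig <- array(0, rep(n, 3))
  eps[rr < radius] <- eps_in
  sig[rr < radius] <- sigma_in
  list(eps = eps, sigma = sig)
}

cached <- local({
  env <- new.env()
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})

default_array <- function() cached("array", build_array())

operator_grid10 <- function() {
  cached("op10", build_forward_operator(default_array(), 10, 0.24, "full"))
}
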