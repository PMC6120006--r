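# Shared fixtures. Blobs with unequal masses have a nonzero Gamma(1)
# (center of mass != centroid), which exercises the odd-rank terms.

weighted_blob <- function(n, seed, scale = 1) {
  set.seed(seed)
  blob_template(matrix(rnorm(3 * n, sd = scale), ncol = 3),
                masses = runif(n, 0.5, 3),
                label = sprintf("wblob-%d-%d", n, seed))
}

random_pair_state <- function(seed, n_a = 4, n_b = 6, R = NULL) {
  set.seed(seed)
  ba <- weighted_blob(n_a, seed * 2 + 1)
  bb <- weighted_blob(n_b, seed * 2 + 2)
  if (is.null(R)) R <- runif(1, 6, 15)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  list(A = blob_state(ba, R * dir, quat_normalize(rnorm(4))),
       B = blob_state(bb, c(0, 0, 0), quat_normalize(rnorm(4))))
}

# cached C60 template (built once per test run)
c60_cached <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) tmpl <<- build_c60(1.450, 1.386)
    tmpl
  }
})

atomic_carbon_morse <- function() morse_potential(0.074, 1.3, 4.1)
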