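# Shared small-scale fixtures, built in code at test time.

# compact phantom for projector/OS-EM unit tests (named arguments in ...
# override the compact defaults)
tiny_phantom <- function(n = 24, voxel = 1.2, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(n, n, n), voxel_size = voxel,
         body_axes = c(9, 7, 11), kidney_axes = c(2, 2, 3.2),
         kidney_separation = 8),
    list(...))
  do.call(make_phantom, args)
}

# the pediatric two-exponential uptake model (plateau 0.36)
eq_pediatric <- function() biokinetic_model(0.3, c(-1, 1.2), c(1.1, Inf))

# the adult ICRP 53 reference model
eq_adult <- function() biokinetic_model(0.5, c(-1, 1), c(1, Inf))

# brute-force L1 (median regression) oracle: the optimum of the check loss
# is attained at a coefficient vector interpolating p observations, so
# enumerate all p-subsets
bruteforce_l1_objective <- function(X, y, tau = 0.5) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b)) next
    r <- y - as.numeric(X %*% b)
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}
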