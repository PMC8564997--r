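# Geometry helpers for tests: random rigid motions built independently of
# the package internals (quaternion rotation, Rodrigues parameterization for
# the numeric registration oracle).

rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rand_transform <- function(tmax = 20) {
  rigid_transform(rand_rotation(), runif(3, -tmax, tmax))
}

rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Independent 6-parameter numeric minimizer of the rigid alignment objective
# sum_i ||R s_i + t - t_i||^2, restarted from random rotation vectors.
oracle_align_objective <- function(src, tgt, restarts = 20) {
  obj <- function(par) {
    R <- rodrigues(par[1:3])
    sum((src %*% t(R) + matrix(par[4:6], nrow(src), 3, byrow = TRUE) - tgt)^2)
  }
  best <- Inf
  for (r in seq_len(restarts)) {
    init <- c(runif(3, -pi, pi), colMeans(tgt) - colMeans(src))
    fit <- optim(init, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    fit2 <- optim(fit$par, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit2$value)
  }
  best
}

max_pairwise_distance_change <- function(a, b) {
  max(abs(dist(a) - dist(b)))
}
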