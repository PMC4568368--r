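# Internal helpers: seeded RNG scoping, unit conversions, small math utilities.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a small salt, kept inside the
# 32-bit signed range so set.seed() accepts it on any platform.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 2654435761 + salt) %% 2147483647)
}

UM2_PER_MM2 <- 1e6
UM3_PER_MM3 <- 1e9
UM_PER_MM <- 1e3

# Uniform random directions on the unit sphere (Marsaglia's method).
random_directions <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, n, 3)
  need <- n
  while (need > 0) {
    m <- ceiling(need * 1.4) + 8
    x1 <- runif(m, -1, 1)
    x2 <- runif(m, -1, 1)
    s <- x1^2 + x2^2
    keep <- which(s < 1)
    keep <- keep[seq_len(min(length(keep), need))]
    if (length(keep)) {
      r <- sqrt(1 - s[keep])
      rows <- (n - need) + seq_along(keep)
      out[rows, ] <- cbind(2 * x1[keep] * r, 2 * x2[keep] * r, 1 - 2 * s[keep])
      need <- need - length(keep)
    }
  }
  out
}

# Orthonormal in-plane basis (e1, e2) for a unit normal.
plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    normal[2] * e1[3] - normal[3] * e1[2],
    normal[3] * e1[1] - normal[1] * e1[3],
    normal[1] * e1[2] - normal[2] * e1[1]
  )
  rbind(e1 = e1, e2 = e2, n = normal)
}

# Normal draws truncated at zero (rejection; fine for mu/sigma >~ 1).
rnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

# Moments E[R^k] of a normal(mu, sigma) truncated to (0, Inf).
truncnorm_moment <- function(k, mean, sd) {
  if (sd == 0) return(mean^k)
  z <- pnorm(0, mean, sd, lower.tail = FALSE)
  integrate(function(r) r^k * dnorm(r, mean, sd) / z,
            lower = 0, upper = mean + 12 * sd, rel.tol = 1e-9)$value
}

# Which of `pts` (n x 3) fall inside any sphere (centers m x 3, radius r).
# Chunked with early exit: points already hit are dropped from later chunks.
points_in_spheres <- function(pts, centers, radius) {
  n <- nrow(pts)
  hit <- logical(n)
  m <- nrow(centers)
  if (n == 0 || m == 0) return(hit)
  r2 <- radius^2
  alive <- seq_len(n)
  chunk <- 512L
  starts <- seq(1L, m, by = chunk)
  for (s in starts) {
    if (!length(alive)) break
    idx <- s:min(s + chunk - 1L, m)
    cc <- centers[idx, , drop = FALSE]
    p <- pts[alive, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(cc^2), "+") - 2 * tcrossprod(p, cc)
    newly <- rowSums(d2 <= r2) > 0
    hit[alive[newly]] <- TRUE
    alive <- alive[!newly]
  }
  hit
}

# Minimum distance from points to a 3D segment p0--p1.
dist_to_segment <- function(pts, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d^2)
  rel <- sweep(pts, 2, p0)
  tt <- if (len2 > 0) pmin(pmax(rel %*% d / len2, 0), 1) else rep(0, nrow(pts))
  closest <- outer(as.vector(tt), d) + matrix(p0, nrow(pts), 3, byrow = TRUE)
  sqrt(rowSums((pts - closest)^2))
}

# Truncate toward zero at `digits` decimals (with a guard against float fuzz).
trunc_digits <- function(x, digits = 2) {
  f <- 10^digits
  trunc(x * f + sign(x) * 1e-9) / f
}

fmt_mean_sd <- function(mean, sd, digits = 1) {
  sprintf("%.*f (%.*f)", digits, mean, digits, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
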