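# Independent oracles, written from first principles and kept free of the
# package's own code paths.

# entry distance of a ray into an axis-aligned ellipsoid (smallest positive
# root of the line-quadric quadratic); 0 if the origin is inside, NA on miss
oracle_entry <- function(origin, dir, center, semi) {
  if (length(semi) == 1L) semi <- rep(semi, 3L)
  o <- (origin - center) / semi
  d <- dir / semi
  A <- sum(d * d)
  B <- 2 * sum(o * d)
  C <- sum(o * o) - 1
  if (C <= 0) return(0)
  disc <- B * B - 4 * A * C
  if (disc < 0) return(NA_real_)
  t1 <- (-B - sqrt(disc)) / (2 * A)
  if (t1 > 0) t1 else NA_real_
}

# radiological depth of `point` along the source->point ray for an ellipsoid
oracle_depth <- function(source, point, center, semi) {
  L <- sqrt(sum((point - source)^2))
  dir <- (point - source) / L
  t <- oracle_entry(source, dir, center, semi)
  if (is.na(t) || t > L) 0 else L - t
}

# radial surface distance of an axis-aligned ellipsoid along unit vector u
oracle_radius <- function(u, semi) 1 / sqrt(sum((u / semi)^2))

# hand-rolled beamlet-model summation (loop form, no package helpers)
oracle_point_dose <- function(beamlets, point, skull_center, skull_semi, params,
                              duration) {
  erf0 <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  total <- 0
  for (i in seq_len(nrow(beamlets))) {
    src <- c(beamlets$x[i], beamlets$y[i], beamlets$z[i])
    dep <- oracle_depth(src, point, skull_center, skull_semi)
    if (dep <= 0) next
    r <- sqrt(sum((point - src)^2))
    axis <- c(beamlets$dx[i], beamlets$dy[i], beamlets$dz[i])
    v <- point - src
    along <- sum(v * axis)
    perp <- sqrt(max(0, sum(v * v) - along^2))
    f <- beamlets$focal_mm[i]
    rho <- perp * f / r
    cid <- as.character(beamlets$collimator[i])
    Rc <- params$field_radius[[cid]]
    sc <- params$penumbra[[cid]]
    P <- 0.5 * (erf0((Rc - rho) / sc) + erf0((Rc + rho) / sc)) / erf0(Rc / sc)
    total <- total + params$dose_rate / 192 * params$output_factors[[cid]] *
      exp(-params$mu * (dep - params$d_ref)) * (f / r)^2 * P
  }
  total * duration
}

# exact two-sided Wilcoxon signed-rank p by explicit 2^n enumeration
oracle_wsrt_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  Wall <- numeric(2^n)
  for (i in 0:(2^n - 1)) {
    bits <- bitwAnd(i, 2^(0:(n - 1))) > 0
    Wall[i + 1] <- sum(r[bits])
  }
  mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
}

# exact two-sided Mann-Whitney p by explicit C(n, k) label enumeration,
# U computed by direct pair counting for the smaller group
oracle_mwu_p <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  pooled <- c(a, b)
  n <- length(pooled); k <- length(a)
  u_of <- function(g1, g2) {
    u <- 0
    for (x in g1) for (y in g2) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  U_obs <- u_of(a, b)
  mu <- k * (n - k) / 2
  combos <- combn(n, k)
  Us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# tau-b by explicit O(n^2) concordant/discordant pair counting
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
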