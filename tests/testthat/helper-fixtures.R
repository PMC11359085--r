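# Shared fixtures, built in code at test time.

# A small scene that keeps per-pixel fitting cheap.
tiny_scene <- function(shape = c(10, 10), fps = 10, duration = 30, seed = 1L,
                       ...) {
  skin_scene_config(shape = shape, fps_truth = fps, duration_s = duration,
                    seed = seed, ...)
}

# Cube whose every pixel follows one exact double-exponential curve.
exact_cube <- function(theta = c(32, -2, -0.05, -1, -0.5), shape = c(4, 4),
                       K = 100, fps = 10) {
  y <- generate_trc(theta, K, fps)
  thermal_cube(aperm(array(y, c(K, shape)), c(2, 3, 1)), fps = fps)
}

# Noiseless camera with an identity PSF at a given frame rate.
ideal_profile <- function(fps = 10, shape = c(10, 10)) {
  camera_profile("ideal", fps = fps, fpa = shape, netd_mK = 0, psf_sigma = 0)
}

# Independent brute-force implementations of the feature statistics, used
# as oracles against the package's vectorized versions.
brute_distance <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s) / length(a)
}

brute_energy_difference <- function(a, b) {
  ua <- a - min(a); ub <- b - min(b)
  sa <- 0; sb <- 0
  for (i in seq_along(a)) { sa <- sa + ua[i]^2; sb <- sb + ub[i]^2 }
  sa - sb
}

brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_similitude <- function(set, model) {
  proj <- numeric(ncol(set)); rho <- numeric(ncol(set)); dst <- numeric(ncol(set))
  for (j in seq_len(ncol(set))) {
    proj[j] <- sum(set[, j] * model)
    rho[j] <- brute_pearson(set[, j], model)
    dst[j] <- brute_distance(set[, j], model)
  }
  c(proj_mean = mean(proj), proj_sd = sd(proj),
    rho_mean = mean(rho), rho_sd = sd(rho),
    dist_mean = mean(dst), dist_sd = sd(dst))
}
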