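# geometric masks built in code -----------------------------------------

mk_disk_mask <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  cx <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - cx
  y <- matrix(rep(seq_len(n), times = n), n) - cx
  x^2 + y^2 <= r^2
}

mk_ellipse_mask <- function(a, b, theta = 0, pad = 3L) {
  n <- 2L * ceiling(max(a, b)) + 2L * pad
  cx <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - cx
  y <- matrix(rep(seq_len(n), times = n), n) - cx
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

mk_square_mask <- function(s, pad = 3L) {
  n <- s + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + s), (pad + 1L):(pad + s)] <- TRUE
  m
}

const_nucleus <- function(mask, gray = 117L, calibration = 0.1) {
  nucleus_image(matrix(gray, nrow(mask), ncol(mask)), mask, calibration)
}

random_nucleus <- function(seed = 1L, area_px = 1500, hurst = 0.75,
                           mean_gray = 130, sd_gray = 8.7, clumps = 2) {
  set.seed(seed)
  m <- generate_mask("oval", area_px)
  s <- generate_fbm_surface(hurst, max(32L, max(dim(m))))
  compose_nucleus(m, s, mean_gray, sd_gray, clumps)
}

# small cohort configuration used across pipeline tests
test_config <- function(seed = 7L, n_patients = 2L, nuclei = 3L) {
  generator_config(
    seed = seed,
    n_patients_per_group = n_patients,
    nuclei_per_patient = nuclei,
    group_params = list(
      itd = list(hurst = 0.70, mean_gray = 108, sd_gray = 6.3,
                 clump_density = 0.5, mask_shape = "bilobed",
                 area_um2_range = c(12, 18), flt3_itd = 1L,
                 leuk_meanlog = log(63), leuk_sdlog = 0.03),
      classical = list(hurst = 0.75, mean_gray = 130, sd_gray = 8.7,
                       clump_density = 2.0, mask_shape = "oval",
                       area_um2_range = c(12, 18), flt3_itd = 0L,
                       leuk_meanlog = log(2), leuk_sdlog = 1.2)),
    survival_params = list(
      itd = list(hazard_rate = 0.08, censor_time = 41),
      classical = list(hazard_rate = 0.02, censor_time = 41)))
}

# independent oracles -----------------------------------------------------

# direct pair-enumeration GLCM features (loops, no shared code path)
oracle_glcm_features <- function(gray, mask,
                                 offsets = rbind(c(0, 1), c(1, 0),
                                                 c(1, 1), c(1, -1)),
                                 base = 2) {
  counts <- matrix(0, 256, 256)
  nr <- nrow(gray); nc <- ncol(gray)
  for (k in seq_len(nrow(offsets))) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + offsets[k, 1]; c2 <- c + offsets[k, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- gray[r, c] + 1; j <- gray[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  p <- counts / sum(counts)
  lev <- 0:255
  mu_x <- sum(rowSums(p) * lev); mu_y <- sum(colSums(p) * lev)
  ent <- 0; ctr <- 0; hom <- 0; prom <- 0
  for (i in 1:256) for (j in 1:256) {
    if (p[i, j] > 0) {
      ent <- ent - p[i, j] * log(p[i, j], base = base)
      d2 <- (lev[i] - lev[j])^2
      ctr <- ctr + d2 * p[i, j]
      hom <- hom + p[i, j] / (1 + d2)
      prom <- prom + (lev[i] + lev[j] - mu_x - mu_y)^4 * p[i, j]
    }
  }
  c(entropy = ent, contrast = ctr, local_homogeneity = hom,
    cluster_prominence = prom)
}

# brute-force blanket volumes: u_e(x) = max over 4-geodesic ball of
# (g(y) + e - d(x, y)), the 3D Minkowski dilation with the cone element
oracle_blanket_V <- function(gray, eps_max) {
  nr <- nrow(gray); nc <- ncol(gray)
  V <- numeric(eps_max)
  for (e in seq_len(eps_max)) {
    tot <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      u <- -Inf; b <- Inf
      for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
        d <- abs(r - r2) + abs(c - c2)
        if (d <= e) {
          u <- max(u, gray[r2, c2] + e - d)
          b <- min(b, gray[r2, c2] - e + d)
        }
      }
      tot <- tot + (u - b)
    }
    V[e] <- tot
  }
  V
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# exact two-sided Spearman p via the classical 6*sum(d^2) formula over all
# permutations (valid for tie-free data)
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  perms <- permutations_oracle(n)
  rhos <- apply(perms, 1, function(pm) {
    1 - 6 * sum((rx - ry[pm])^2) / (n * (n^2 - 1))
  })
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# iterative (non-recursive) permutation generator, independent of the
# package's recursive one
permutations_oracle <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    grown <- matrix(0L, 0L, k)
    for (row in seq_len(nrow(out))) {
      for (pos in seq_len(k)) {
        grown <- rbind(grown, append(out[row, ], k, after = pos - 1L))
      }
    }
    out <- grown
  }
  out
}

# Breslow partial log-likelihood written independently for grid search
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    dies <- time == tt & event == 1
    risk <- time >= tt
    ll <- ll + beta * sum(x[dies]) - sum(dies) * log(sum(exp(beta * x[risk])))
  }
  ll
}
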