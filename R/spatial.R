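#' Global Moran's I spatial autocorrelation
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with row-standardized weights: inverse distance (default) or
#' k-nearest-neighbour. Expectation is `-1/(n-1)`; the Z score and two-sided
#' p-value use the randomization (permutation-moment) variance. An optional
#' seeded permutation p-value is available.
#'
#' @param values numeric vector (non-constant).
#' @param coords n x 2 coordinate matrix.
#' @param scheme `"inverse_distance"` or `"knn"`.
#' @param k neighbours for the knn scheme (default 4).
#' @param permutations number of random permutations for an empirical p
#'   (0 = none).
#' @param seed RNG seed for permutations.
#' @param jitter small coordinate jitter applied when duplicate points make
#'   inverse distances infinite (default 0 = error instead).
#' @return list with `moran_i`, `expected_i`, `sd_i`, `z_score`, `p_value`,
#'   `p_permutation` (NA unless requested), `weight_scheme`.
#' @export
moranI <- function(values, coords, scheme = c("inverse_distance", "knn"),
                   k = 4, permutations = 0, seed = 1L, jitter = 0) {
  scheme <- match.arg(scheme)
  x <- as.numeric(values)
  n <- length(x)
  coords <- as.matrix(coords)
  stopifnot(n >= 4, nrow(coords) == n)
  if (sd(x) == 0)
    return(list(moran_i = NA_real_, expected_i = -1 / (n - 1), sd_i = NA_real_,
                z_score = NA_real_, p_value = NA_real_,
                p_permutation = NA_real_, weight_scheme = scheme))
  D <- as.matrix(dist(coords))
  if (scheme == "inverse_distance") {
    if (any(D[upper.tri(D)] == 0)) {
      if (jitter <= 0)
        stop("duplicate coordinates under inverse-distance weights; set jitter > 0")
      set.seed(seed)
      coords <- coords + matrix(rnorm(2 * n, 0, jitter), n, 2)
      D <- as.matrix(dist(coords))
    }
    W <- 1 / D
    diag(W) <- 0
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(min(k, n - 1))]
      idx <- seq_len(n)[-i][nb]
      W[i, idx] <- 1
    }
  }
  W <- W / rowSums(W)
  z <- x - mean(x)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * outer(z, z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(varI)
  Z <- (I - EI) / sdI
  p <- 2 * pnorm(abs(Z), lower.tail = FALSE)
  pperm <- NA_real_
  if (permutations > 0) {
    set.seed(seed)
    Iperm <- replicate(permutations, {
      zz <- sample(z)
      (n / S0) * sum(W * outer(zz, zz)) / sum(zz^2)
    })
    pperm <- (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (permutations + 1)
  }
  list(moran_i = I, expected_i = EI, sd_i = sdI, z_score = Z, p_value = p,
       p_permutation = pperm, weight_scheme = scheme)
}

#' Gaussian kernel intensity surface
#'
#' Unweighted first-order point intensity and, when `values` are supplied,
#' the Nadaraya-Watson weighted surface, evaluated on a regular grid
#' covering the bounding box with a 10% margin. The default bandwidth is
#' Silverman's rule on the coordinates.
#'
#' @param coords n x 2 coordinates.
#' @param values optional per-point values for the weighted surface.
#' @param bandwidth kernel standard deviation (> 0).
#' @param grid_n grid resolution per axis (default 64).
#' @return list with `x`, `y` (grid axes), `intensity` (points per unit
#'   area) and `weighted` (NULL without values).
#' @export
kernelIntensity <- function(coords, values = NULL, bandwidth = NULL,
                            grid_n = 64) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(bandwidth)) {
    s <- mean(apply(coords, 2, sd))
    if (!is.finite(s) || s == 0) s <- 1
    bandwidth <- 1.06 * s * n^(-1 / 5)
  }
  stopifnot(bandwidth > 0)
  rng <- apply(coords, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  gx <- seq(rng[1, 1] - 0.1 * span[1], rng[2, 1] + 0.1 * span[1],
            length.out = grid_n)
  gy <- seq(rng[1, 2] - 0.1 * span[2], rng[2, 2] + 0.1 * span[2],
            length.out = grid_n)
  kx <- outer(gx, coords[, 1], function(a, b) stats::dnorm(a - b, sd = bandwidth))
  ky <- outer(gy, coords[, 2], function(a, b) stats::dnorm(a - b, sd = bandwidth))
  dens <- matrix(0, grid_n, grid_n)
  wsum <- matrix(0, grid_n, grid_n)
  for (i in seq_len(n)) {
    kk <- outer(kx[, i], ky[, i])
    dens <- dens + kk
    if (!is.null(values)) wsum <- wsum + kk * values[i]
  }
  list(x = gx, y = gy, intensity = dens,
       weighted = if (is.null(values)) NULL else wsum / pmax(dens, 1e-300))
}

#' Nearest-neighbour distances
#'
#' @param coords n x 2 coordinates (n >= 2).
#' @return per-point Euclidean distance to the nearest other point.
#' @export
nearestNeighborDistances <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}
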