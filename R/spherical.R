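# Spherical-spline machinery for scalp interpolation and the current
# source density (surface Laplacian) transform, following the classic
# G/H-matrix formulation: for electrodes at unit-sphere positions with
# pairwise cosine angles x,
#   g(x) = (1/4pi) sum_n (2n+1) / (n (n+1))^m     P_n(x)
#   h(x) = (1/4pi) sum_n (2n+1) / (n (n+1))^(m-1) P_n(x)
# The spline coefficients c solve (G + lambda I) c + d 1 = z with
# sum(c) = 0; interpolation evaluates d + g(x) c at new sites and the CSD
# is H c (uV/m^2 up to the squared head radius, taken as 1).

# Legendre-series sums of g and h for a matrix of cosine angles.
spline_gh <- function(cosang, m = 4, n_terms = 50) {
  x <- pmin(pmax(cosang, -1), 1)   # clamp; keeps matrix dims
  p_prev <- matrix(1, nrow(x), ncol(x))   # P_0
  p_cur <- x                              # P_1
  g <- matrix(0, nrow(x), ncol(x))
  h <- matrix(0, nrow(x), ncol(x))
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      p_prev <- p_cur
      p_cur <- p_next
    }
    nn1 <- n * (n + 1)
    g <- g + (2 * n + 1) / nn1^m * p_cur
    h <- h + (2 * n + 1) / nn1^(m - 1) * p_cur
  }
  list(g = g / (4 * pi), h = h / (4 * pi))
}

cosine_angles <- function(xyz_a, xyz_b = xyz_a) {
  tcrossprod(as.matrix(xyz_a), as.matrix(xyz_b))
}

scalp_xyz <- function(montage, labels = montage$label[montage$is_scalp]) {
  m <- montage[match(labels, montage$label), c("x", "y", "z")]
  as.matrix(m)
}

# Fit spherical-spline coefficients for each time sample (columns of Z,
# electrodes in rows). Returns list(C = coefficients, d = constants).
spline_fit <- function(G, Z, lambda = 1e-5) {
  ne <- nrow(G)
  A <- rbind(cbind(G + lambda * diag(ne), rep(1, ne)),
             c(rep(1, ne), 0))
  sol <- solve(A, rbind(Z, 0))
  list(C = sol[seq_len(ne), , drop = FALSE],
       d = sol[ne + 1, , drop = TRUE])
}
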