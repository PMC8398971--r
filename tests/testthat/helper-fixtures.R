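# Shared fixtures: random matrices, random exciton Hamiltonians and the
# grid-sampling overlap oracle.  Everything is built in code under fixed
# seeds.

rand_sym <- function(n, scale = 0.2, diag_center = 5.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n, sd = scale), n, n)
  H <- (A + t(A)) / 2
  diag(H) <- diag_center + rnorm(n, sd = 0.3)
  H
}

# random full-row-rank overlap matrix with unit-norm-ish rows
rand_overlap <- function(n_ref, n_adiab, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(rnorm(n_ref * n_adiab), n_ref, n_adiab)
  S / sqrt(rowSums(S^2))
}

rand_rotation <- function() {
  q <- svd(matrix(rnorm(9), 3, 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random labelled LE+CT Hamiltonian fixture with positions and dipoles
rand_exciton_ham <- function(n_sites = 12, n_ct_pairs = 8,
                             n_ct_per_direction = 2, seed = 1,
                             mag = 0) {
  set.seed(seed)
  pairs <- data.frame(i = seq_len(n_ct_pairs),
                      j = seq_len(n_ct_pairs) + 1L)
  basis <- exciton_basis(seq_len(n_sites), ct_pairs = pairs,
                         n_ct_per_direction = n_ct_per_direction)
  n <- nrow(basis)
  H <- rand_sym(n)
  pos <- matrix(rnorm(3 * n, sd = 4), n, 3)
  mu <- matrix(rnorm(3 * n, sd = 0.6), n, 3)
  mg <- matrix(rnorm(3 * n, sd = mag), n, 3)
  exciton_hamiltonian(basis, H, pos, mu, mg)
}

# grid-sampling oracle for the stacking overlap area (same convex-hull
# outline definition as the implementation, independent area estimator)
grid_overlap_oracle <- function(site_i, site_j, h = 0.005) {
  xi <- site_coords(site_i, site_i$ring_atoms)
  xj <- site_coords(site_j, site_j$ring_atoms)
  pli <- base_plane(xi); plj <- base_plane(xj)
  nj <- plj$normal * sign(sum(pli$normal * plj$normal))
  normal <- (pli$normal + nj) / sqrt(sum((pli$normal + nj)^2))
  point <- (pli$point + plj$point) / 2
  B <- frdex:::.plane_basis(normal)
  pi2 <- sweep(xi, 2, point) %*% B
  pj2 <- sweep(xj, 2, point) %*% B
  hull <- function(p) {
    v <- p[grDevices::chull(p[, 1], p[, 2]), , drop = FALSE]
    if (frdex:::.poly_area_signed(v) < 0) v <- v[rev(seq_len(nrow(v))), ]
    v
  }
  hi <- hull(pi2); hj <- hull(pj2)
  inside <- function(px, py, v) {
    ok <- rep(TRUE, length(px))
    m <- nrow(v)
    for (k in seq_len(m)) {
      a <- v[k, ]; b <- v[if (k == m) 1 else k + 1, ]
      ok <- ok & ((b[1] - a[1]) * (py - a[2]) -
                  (b[2] - a[2]) * (px - a[1]) >= 0)
    }
    ok
  }
  xr <- range(c(hi[, 1], hj[, 1])); yr <- range(c(hi[, 2], hj[, 2]))
  gx <- seq(xr[1], xr[2], by = h); gy <- seq(yr[1], yr[2], by = h)
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  sum(inside(px, py, hi) & inside(px, py, hj)) * h * h
}

# tiny deterministic two-site fixture with attached monomer data
dimer_fixture <- function(rise = 3.4, twist = 0, seed = 1) {
  spec <- generator_spec(seed = seed, n_tetrads = 2, rise = rise,
                         twist = twist)
  stk <- make_ideal_stack(spec)
  sites <- attach_all_monomer_data(stk$sites, spec)
  list(spec = spec, stack = stk,
       m = sites[[1]], n = sites[[5]])   # a stacked pair
}

expect_sym <- function(H, tol = 1e-10) {
  expect_lt(max(abs(H - t(H))), tol)
}
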