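# Eigenstates, rotational/oscillator strengths and broadened curves.

test_that("diagonalize: closed forms and algebraic reconstruction", {
  expect_equal(diagonalize(matrix(c(5.0, 0.1, 0.1, 5.0), 2, 2))$energies,
               c(4.9, 5.1), tolerance = 1e-12)
  set.seed(61)
  H <- rand_sym(20)
  st <- diagonalize(H)
  rec <- st$coefficients %*% (t(st$coefficients) * st$energies)
  expect_lt(max(abs(H - rec)), 1e-9)
  expect_lt(max(abs(crossprod(st$coefficients) - diag(20))), 1e-8)
  expect_error(diagonalize(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("coplanar systems with no intrinsic magnetic moment have zero CD", {
  # positions and dipoles all in the xy-plane
  set.seed(62)
  b <- exciton_basis(1:4)
  n <- nrow(b)
  pos <- cbind(matrix(rnorm(2 * n, sd = 4), n, 2), 0)
  mu <- cbind(matrix(rnorm(2 * n, sd = 0.7), n, 2), 0)
  ham <- exciton_hamiltonian(b, rand_sym(n), pos, mu, matrix(0, n, 3))
  st <- diagonalize(ham)
  expect_lt(max(abs(st$R)), 1e-12)
})

test_that("a twisted homodimer gives equal and opposite rotational strengths", {
  b <- exciton_basis(1:2)
  # one bright state per site (Lb dark), dipoles twisted about the stack axis
  mu <- rbind(c(1, 0, 0), c(0, 0, 0), cos(pi / 6) * c(1, 0, 0) +
                sin(pi / 6) * c(0, 1, 0), c(0, 0, 0))
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 3.4), c(0, 0, 3.4))
  H <- diag(c(5.3, 9.9, 5.3, 9.9))
  H[1, 3] <- H[3, 1] <- 0.05
  ham <- exciton_hamiltonian(b, H, pos, mu, matrix(0, 4, 3))
  st <- diagonalize(ham)
  bright <- order(abs(st$R), decreasing = TRUE)[1:2]
  expect_equal(st$R[bright[1]], -st$R[bright[2]], tolerance = 1e-10)
  expect_gt(abs(st$R[bright[1]]), 1e-3)
  expect_lt(abs(sum(st$R)), 1e-10)
})

test_that("rotational strengths are invariant under rigid motions of the system", {
  ham <- rand_exciton_ham(n_sites = 12, n_ct_pairs = 8,
                          n_ct_per_direction = 2, seed = 63)
  expect_equal(nrow(ham$basis), 24 + 32)
  st <- diagonalize(ham)
  R0 <- st$R
  scale_ref <- max(abs(R0))
  set.seed(64)
  for (rep in 1:5) {
    t <- rnorm(3, sd = 1e3)
    ham_t <- ham; ham_t$positions <- sweep(ham$positions, 2, t, "+")
    Rt <- diagonalize(ham_t)$R
    expect_lt(max(abs(Rt - R0)) / scale_ref, 1e-10)
    Rot <- rand_rotation()
    ham_r <- ham
    ham_r$positions <- ham$positions %*% Rot
    ham_r$elec_tdip <- ham$elec_tdip %*% Rot
    ham_r$mag_tdip <- ham$mag_tdip %*% Rot
    Rr <- diagonalize(ham_r)$R
    expect_lt(max(abs(Rr - R0)) / scale_ref, 1e-10)
  }
  # the named displacement: (1e3, -1e3, 42) Angstrom
  ham_t <- ham
  ham_t$positions <- sweep(ham$positions, 2, c(1e3, -1e3, 42), "+")
  expect_lt(max(abs(diagonalize(ham_t)$R - R0)) / scale_ref, 1e-10)
})

test_that("the rotatory trace equals the intrinsic total (sum rule)", {
  # zero intrinsic magnetic moments: trace must vanish
  ham0 <- rand_exciton_ham(n_sites = 6, n_ct_pairs = 4, seed = 65, mag = 0)
  st0 <- diagonalize(ham0)
  expect_lt(abs(sum(st0$R)) / max(abs(st0$R)), 1e-10)
  # nonzero intrinsic moments: trace equals the basis-state total
  ham1 <- rand_exciton_ham(n_sites = 6, n_ct_pairs = 4, seed = 66,
                           mag = 0.05)
  st1 <- diagonalize(ham1)
  intrinsic <- sum(rowSums(ham1$elec_tdip * ham1$mag_tdip)) *
    frdex_constants()$rot_au_cgs
  expect_equal(sum(st1$R), intrinsic, tolerance = 1e-10)
})

test_that("oscillator strengths: monomer value, H-dimer concentration, sum rule", {
  const <- frdex_constants()
  # single monomer
  b1 <- exciton_basis(1)
  mu1 <- rbind(c(1, 0, 0), c(0, 1, 0))
  h1 <- exciton_hamiltonian(b1, diag(c(5.3, 5.6)), matrix(0, 2, 3), mu1,
                            matrix(0, 2, 3))
  st1 <- diagonalize(h1)
  expect_equal(st1$f[1], (2 / 3) * (5.3 / const$hartree_ev) * 1,
               tolerance = 1e-12)
  # ideal H-dimer: parallel dipoles, positive coupling -> dark lower state
  b2 <- exciton_basis(1:2)
  mu2 <- rbind(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  H2 <- diag(c(5.3, 9.9, 5.3, 9.9)); H2[1, 3] <- H2[3, 1] <- 0.08
  pos2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 3.4), c(0, 0, 3.4))
  st2 <- diagonalize(exciton_hamiltonian(b2, H2, pos2, mu2,
                                         matrix(0, 4, 3)))
  expect_lt(st2$f[1], 1e-12)
  f_mono <- (2 / 3) * (5.3 / const$hartree_ev)
  expect_equal(st2$f[2], (2 / 3) * ((5.3 + 0.08) / const$hartree_ev) * 2,
               tolerance = 1e-10)
  # equal-energy unitary mixing conserves total f exactly
  n <- 6
  set.seed(67)
  mu <- matrix(rnorm(3 * n), n, 3)
  H <- matrix(0.02, n, n); diag(H) <- 5.5   # near-degenerate diagonal
  Hd <- diag(rep(5.5, n))
  bas <- exciton_basis(seq_len(n / 2))
  st_mix <- diagonalize(exciton_hamiltonian(bas, H, matrix(0, n, 3), mu,
                                            matrix(0, n, 3)))
  st_diag <- diagonalize(exciton_hamiltonian(bas, Hd, matrix(0, n, 3), mu,
                                             matrix(0, n, 3)))
  # the squared state dipoles are exactly conserved under unitary mixing;
  # f picks up only the tiny eigenvalue spread of the coupling
  M2 <- function(st) sum(crossprod(st$coefficients, mu)^2)
  expect_equal(M2(st_mix), M2(st_diag), tolerance = 1e-10)
  expect_equal(sum(st_mix$f), sum(st_diag$f), tolerance = 0.02)
})

test_that("stick broadening: peak position, conservation and sigma scaling", {
  cfg <- frdex_config()
  cur <- stick_to_curve(data.frame(energy = 5.11, value = 1))
  peak_e <- cur$energy[which.max(cur$intensity)]
  expect_equal(peak_e, 5.11 + cfg$shift_ev, tolerance = 0.01)
  expect_equal(frdex_constants()$ev_nm / peak_e, 291, tolerance = 1)
  # two opposite sticks integrate to ~0 over energy
  cur2 <- stick_to_curve(data.frame(energy = c(4.6, 5.6),
                                    value = c(1, -1)),
                         grid_nm = seq(150, 600, 0.25))
  e <- rev(cur2$energy); i <- rev(cur2$intensity)
  integral <- sum((i[-1] + i[-length(i)]) / 2 * diff(e))
  expect_lt(abs(integral), 1e-3)
  # halving sigma doubles the height of an isolated stick
  c_a <- stick_to_curve(data.frame(energy = 5.11, value = 1), sigma = 0.21)
  c_b <- stick_to_curve(data.frame(energy = 5.11, value = 1), sigma = 0.105)
  expect_equal(max(c_b$intensity) / max(c_a$intensity), 2, tolerance = 1e-3)
  expect_warning(z <- stick_to_curve(data.frame(energy = numeric(),
                                                value = numeric())),
                 "empty")
  expect_true(all(z$intensity == 0))
})

test_that("curve averaging is the pointwise mean", {
  set.seed(68)
  mk <- function(v) spectrum_curve(seq(220, 340, 0.5), v, -0.85, 0.21)
  v <- rnorm(241)
  expect_equal(average_curves(list(mk(v), mk(v)))$intensity, v)
  expect_equal(average_curves(list(mk(v), mk(-v)))$intensity, rep(0, 241))
  curves <- lapply(1:10, function(i) mk(rnorm(241)))
  expect_equal(average_curves(curves)$intensity,
               Reduce(`+`, lapply(curves, `[[`, "intensity")) / 10,
               tolerance = 1e-12)
  bad <- spectrum_curve(seq(220, 340, 1), rnorm(121), -0.85, 0.21)
  expect_error(average_curves(list(mk(v), bad)), "identical grid")
})

test_that("peak normalization scales, reuses factors and is idempotent", {
  grid <- seq(220, 340, 0.5)
  e <- frdex:::.nm2ev(grid)
  y <- 2 * exp(-((e - 4.3)^2) / (2 * 0.04)) - 1.5 * exp(-((e - 4.9)^2) /
                                                          (2 * 0.04))
  cur <- spectrum_curve(grid, y, -0.85, 0.21)
  nrm <- normalize_to_peak(cur, reference = 1)
  # the lowest-energy (longest-wavelength) peak is the positive lobe at
  # 4.3 eV; the expected factor is 1 over its discrete-grid height
  expect_equal(nrm$normalization$scale, 1 / max(y[grid > 270]),
               tolerance = 1e-9)
  expect_equal(max(nrm$intensity), 1, tolerance = 1e-9)
  # reusing the stored factor does NOT force the sibling's peak to 1
  sib <- spectrum_curve(grid, 0.6 * y, -0.85, 0.21)
  sib_n <- normalize_to_peak(sib, scale = nrm$normalization$scale)
  expect_equal(max(sib_n$intensity), 0.6, tolerance = 1e-6)
  # normalizing twice to the same target is idempotent
  again <- normalize_to_peak(nrm, reference = 1)
  expect_equal(again$intensity, nrm$intensity, tolerance = 1e-9)
  flat <- spectrum_curve(grid, rep(0, length(grid)), -0.85, 0.21)
  expect_error(normalize_to_peak(flat), "flat")
})

test_that("spectrum TSV writer emits the curve and its metadata", {
  cur <- stick_to_curve(data.frame(energy = 5.11, value = 1),
                        meta = list(id = "m1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(cur, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$intensity, cur$intensity, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$shift_applied, cur$shift_applied)
  expect_equal(meta$sigma, cur$sigma)
})
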