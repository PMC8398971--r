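# Loewdin diabatization: transform properties, exact parameter recovery and
# phase handling.

test_that("lowdin transform handles identity and permutation overlaps", {
  S <- diag(4)
  D <- lowdin_transform(reference_overlap(paste0("r", 1:4), S))
  expect_equal(unname(D), diag(4), tolerance = 1e-12)
  P <- diag(4)[c(2, 4, 1, 3), ]
  DP <- lowdin_transform(reference_overlap(paste0("r", 1:4), P))
  expect_equal(unname(DP), t(P), tolerance = 1e-12)
  E <- c(5.0, 5.2, 5.4, 5.6)
  Hd <- diabatic_hamiltonian(DP, E)
  expect_equal(unname(diag(Hd)), E[c(2, 4, 1, 3)], tolerance = 1e-12)
})

test_that("a single reference spread over two states averages their energies", {
  # S = (1/sqrt(2)) (1, 1): hand evaluation gives H_d = (E1+E2)/2
  S <- matrix(1 / sqrt(2), 1, 2)
  D <- lowdin_transform(reference_overlap("r1", S))
  Hd <- diabatic_hamiltonian(D, c(5.0, 6.0))
  expect_equal(as.numeric(Hd), 5.5, tolerance = 1e-12)
})

test_that("D has orthonormal columns for random full-rank overlaps", {
  set.seed(31)
  worst <- 0
  for (i in 1:1000) {
    n_ref <- sample(1:6, 1)
    n_ad <- n_ref + sample(0:6, 1)
    D <- lowdin_transform(rand_overlap(n_ref, n_ad))
    worst <- max(worst, max(abs(crossprod(D) - diag(n_ref))))
  }
  expect_lt(worst, 1e-8)
})

test_that("D is the closest column-orthonormal matrix to t(S) (brute force)", {
  set.seed(32)
  S <- rand_overlap(2, 3)
  D <- lowdin_transform(S)
  obj <- function(M) sum((M - t(S))^2)
  best_rand <- Inf
  for (i in 1:4000) {
    # random 3x2 orthonormal-column matrix
    Q <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
    if (runif(1) < 0.5) Q[, 1] <- -Q[, 1]
    best_rand <- min(best_rand, obj(Q))
  }
  expect_lte(obj(D), best_rand + 1e-12)
})

test_that("round-trip recovery: eigendecomposition oracle to machine precision", {
  for (seed in 1:5) {
    n <- c(4, 6, 8, 12, 16)[seed]
    H_true <- rand_sym(n, seed = 100 + seed)
    labels <- paste0("d", seq_len(n))
    sc <- make_consistent_sc(list(labels = labels, H = H_true,
                                  elec_tdip = matrix(rnorm(3 * n), n, 3),
                                  mag_tdip = matrix(0, n, 3)))
    res <- diabatize_sc(sc$ref, sc$adia)
    expect_lt(max(abs(res$H_d[labels, labels] - H_true)), 1e-10)
  }
  # the printed 2x2 example: off-diagonal coupling recovered
  H2 <- matrix(c(5.0, 0.2, 0.2, 5.4), 2, 2)
  sc2 <- make_consistent_sc(list(labels = c("a", "b"), H = H2,
                                 elec_tdip = matrix(0, 2, 3),
                                 mag_tdip = matrix(0, 2, 3)))
  res2 <- diabatize_sc(sc2$ref, sc2$adia)
  expect_equal(res2$H_d["a", "b"], 0.2, tolerance = 1e-12)
})

test_that("truncating a weakly overlapping state perturbs H_d within bounds", {
  set.seed(33)
  # 6-state model: 5 coupled states + 1 near-decoupled spectator high state
  H <- rand_sym(5, seed = 34)
  H6 <- rbind(cbind(H, rep(1e-9, 5)), c(rep(1e-9, 5), 9.0))
  labels <- paste0("d", 1:6)
  sc_full <- make_consistent_sc(list(labels = labels, H = H6,
                                     elec_tdip = matrix(0, 6, 3),
                                     mag_tdip = matrix(0, 6, 3)))
  # drop the highest adiabatic state; keep only the 5 reference states that
  # overlap the kept space
  sc_tr <- make_consistent_sc(list(labels = labels, H = H6,
                                   elec_tdip = matrix(0, 6, 3),
                                   mag_tdip = matrix(0, 6, 3)),
                              n_adiabatic = 5)
  keep <- paste0("d", 1:5)
  ref_tr <- reference_overlap(keep, sc_tr$ref$S[keep, , drop = FALSE])
  res_tr <- diabatize_sc(ref_tr, sc_tr$adia)
  expect_lt(max(abs(res_tr$H_d[keep, keep] - H)), 1e-6)
})

test_that("reducing the adiabatic space never improves recovery", {
  # 8 model states weakly coupled to 4 higher spectator states; the
  # reference set stays the 8 model states while the adiabatic space
  # shrinks from 12 to 8
  for (seed in 41:44) {
    set.seed(seed)
    H8 <- rand_sym(8, seed = seed)
    C <- matrix(rnorm(8 * 4, sd = 0.03), 8, 4)
    H12 <- rbind(cbind(H8, C), cbind(t(C), diag(4) * 9 + rand_sym(4) * 0.1))
    H12 <- (H12 + t(H12)) / 2
    labels <- paste0("d", 1:12)
    model <- labels[1:8]
    errs <- vapply(c(12, 11, 10, 9, 8), function(nad) {
      sc <- make_consistent_sc(list(labels = labels, H = H12,
                                    elec_tdip = matrix(0, 12, 3),
                                    mag_tdip = matrix(0, 12, 3)),
                               n_adiabatic = nad)
      S <- if (inherits(sc$ref, "reference_overlap")) sc$ref$S else sc$ref$S
      ref <- reference_overlap(model, S[model, , drop = FALSE])
      res <- suppressWarnings(diabatize_sc(ref, sc$adia))
      # error against the effective 8-state model (the full model block)
      max(abs(res$H_d[model, model] - H8))
    }, numeric(1))
    expect_true(all(diff(errs) > -1e-10))
    expect_gt(errs[5], errs[1])
  }
})

test_that("phase fixing makes H_d invariant to arbitrary sign flips", {
  set.seed(35)
  S <- rand_overlap(3, 4)
  rownames(S) <- paste0("r", 1:3)
  E <- c(5.0, 5.3, 5.6, 6.0)
  base_ref <- fix_phases(reference_overlap(paste0("r", 1:3), S))
  H_base <- diabatic_hamiltonian(lowdin_transform(base_ref), E)
  expect_equal(fix_phases(base_ref)$S, base_ref$S)  # idempotent / unchanged
  # brute force over all column sign patterns of a 3x4 S
  for (mask in 0:15) {
    signs <- ifelse(bitwAnd(mask, 2^(0:3)) > 0, -1, 1)
    ref2 <- fix_phases(reference_overlap(paste0("r", 1:3),
                                         sweep(S, 2, signs, "*")))
    H2 <- diabatic_hamiltonian(lowdin_transform(ref2), E)
    expect_lt(max(abs(H2 - H_base)), 1e-12)
  }
})

test_that("phase fixing leaves diabatized properties gauge invariant", {
  set.seed(36)
  n <- 5
  H_true <- rand_sym(n, seed = 37)
  labels <- paste0("d", seq_len(n))
  props <- matrix(rnorm(3 * n), n, 3)
  sc <- make_consistent_sc(list(labels = labels, H = H_true,
                                elec_tdip = props,
                                mag_tdip = matrix(0, n, 3)))
  res1 <- diabatize_sc(sc$ref, sc$adia)
  # negate one adiabatic column (and its properties, as an upstream code
  # with a different phase convention would)
  S2 <- sc$ref$S; S2[, 2] <- -S2[, 2]
  adia2 <- sc$adia; adia2$elec_tdip[2, ] <- -adia2$elec_tdip[2, ]
  res2 <- diabatize_sc(reference_overlap(labels, S2), adia2)
  expect_lt(max(abs(res1$elec_tdip - res2$elec_tdip)), 1e-10)
  expect_lt(max(abs(res1$H_d - res2$H_d)), 1e-10)
  # and the generator round-trip recovers the true dipoles
  expect_lt(max(abs(res1$elec_tdip[labels, ] - props)), 1e-10)
})

test_that("transform_properties is the plain linear map by columns of D", {
  props <- matrix(rnorm(12), 4, 3)
  expect_equal(transform_properties(diag(4), props), props,
               ignore_attr = TRUE)
  P <- diag(4)[, c(3, 1, 4, 2)]
  expect_equal(unname(transform_properties(P, props)),
               props[c(3, 1, 4, 2), ], tolerance = 1e-12)
  expect_error(transform_properties(diag(4), props[1:3, ]), "per adiabatic")
})

test_that("rank-deficient overlap is reported, not silently dropped", {
  S <- rbind(c(1, 0, 0), c(1, 0, 0)) / sqrt(1)
  expect_error(lowdin_transform(reference_overlap(c("a", "b"), S)),
               "rank-deficient")
})

test_that("low completeness triggers a warning naming the state", {
  set.seed(38)
  S <- rand_overlap(2, 4)
  S[2, ] <- S[2, ] * 0.3    # row norm 0.3 < 0.5
  rownames(S) <- c("good", "poor")
  adia <- adiabatic_set("sc", sort(rnorm(4, 5.5, 0.2)),
                        matrix(0, 4, 3), matrix(0, 4, 3))
  expect_warning(diabatize_sc(reference_overlap(c("good", "poor"), S), adia),
                 "poor")
})

test_that("pair blocks expose every coupling class of the two-site model", {
  fx <- dimer_fixture()
  ht <- make_pair_h_true(fx$spec, fx$m, fx$n, 2)
  sc <- make_consistent_sc(ht)
  blk <- build_pair_block(sc$ref, sc$adia, 2)
  expect_equal(blk$sites, c(1L, 5L))
  expect_lt(max(abs(blk$H_d[ht$labels, ht$labels] - ht$H)), 1e-10)
  # all 4 CT labels in the minimal setting
  lab <- parse_labels(blk$labels)
  expect_equal(sum(lab$kind == "CT"), 4)
  # representative couplings: LE-LE cross site, LE-CT, CT-CT opposite
  expect_equal(pair_coupling(blk, le_label(1, "La"), le_label(5, "Lb")),
               ht$H[le_label(1, "La"), le_label(5, "Lb")], tolerance = 1e-10)
  expect_equal(pair_coupling(blk, le_label(1, "La"), ct_label(1, 5, 1)),
               ht$H[le_label(1, "La"), ct_label(1, 5, 1)], tolerance = 1e-10)
  expect_equal(pair_coupling(blk, ct_label(1, 5, 1), ct_label(5, 1, 2)),
               ht$H[ct_label(1, 5, 1), ct_label(5, 1, 2)], tolerance = 1e-10)
  # a CT-free reference set yields an LE-only block
  keep <- ht$labels[1:4]
  ref0 <- reference_overlap(keep, sc$ref$S[keep, , drop = FALSE])
  blk0 <- suppressWarnings(build_pair_block(ref0, sc$adia, 0))
  expect_true(all(parse_labels(blk0$labels)$kind == "LE"))
  # wrong CT count is rejected
  expect_error(build_pair_block(sc$ref, sc$adia, 6), "expected 6 CT")
})

test_that("intra parameters average pair blocks and recover strand models", {
  fx <- dimer_fixture()
  ht <- make_pair_h_true(fx$spec, fx$m, fx$n, 2)
  sc <- make_consistent_sc(ht)
  blk <- build_pair_block(sc$ref, sc$adia, 2)
  intra1 <- build_intra_params("pair_averaged", pairs = list(blk))
  expect_equal(unname(intra1$e_la[1]), ht$H[le_label(1, "La"),
                                            le_label(1, "La")],
               tolerance = 1e-10)
  # a site present in two blocks with energies 4.9 / 5.1 averages to 5.0
  fake <- function(e) {
    lab <- c(le_label(1, "La"), le_label(1, "Lb"))
    list(labels = lab,
         H_d = matrix(c(e, 0.01, 0.01, e + 0.3), 2, 2,
                      dimnames = list(lab, lab)))
  }
  intra2 <- build_intra_params("pair_averaged",
                               pairs = list(fake(4.9), fake(5.1)))
  expect_equal(unname(intra2$e_la[1]), 5.0, tolerance = 1e-12)
  # strand-mode recovery of known site energies
  spec <- generator_spec()
  stk <- make_ideal_stack(spec)
  sites <- attach_all_monomer_data(stk$sites, spec)
  strand <- sites[c(1, 5, 9)]
  hs <- make_le_sc_h_true(spec, strand)
  scs <- make_consistent_sc(hs)
  res <- diabatize_sc(scs$ref, scs$adia)
  intra3 <- build_intra_params("strand", sc_results = list(res))
  expect_equal(intra3$e_la[["1"]],
               hs$H[le_label(1, "La"), le_label(1, "La")], tolerance = 1e-10)
  expect_equal(unname(intra3$v_lalb[1]), spec$v_lalb, tolerance = 1e-10)
  # update_couplings = FALSE keeps couplings out of the strand update
  intra4 <- build_intra_params("strand", sc_results = list(res),
                               update_couplings = FALSE)
  expect_equal(unname(intra4$v_lalb), rep(0, 3))
})

test_that("parametrization interchange files round-trip", {
  spec <- generator_spec(n_tetrads = 2)
  stk <- make_ideal_stack(spec)
  par <- make_parametrization(stk, spec)
  f <- withr::local_tempfile(fileext = ".json")
  write_parametrization_json(par, f)
  par2 <- read_parametrization_json(f)
  expect_equal(length(par2$scs), length(par$scs))
  expect_equal(par2$monomers$G$states$La$charges,
               par$monomers$G$states$La$charges, tolerance = 1e-12)
  i <- 3
  expect_equal(par2$scs[[i]]$ref$S, par$scs[[i]]$ref$S, tolerance = 1e-12)
  expect_equal(par2$scs[[i]]$adia$energies, par$scs[[i]]$adia$energies,
               tolerance = 1e-12)
  expect_equal(par2$scs[[i]]$adia$elec_tdip, par$scs[[i]]$adia$elec_tdip,
               tolerance = 1e-12, ignore_attr = TRUE)
})
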