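# Synthetic parametrization generator: idealized quadruplex geometries,
# monomer transition data, and internally consistent supramolecular-complex
# adiabatic data derived from a known "true" diabatic model.  It stands in
# for the upstream quantum-chemistry step so that diabatization and the full
# pipeline are verifiable by exact parameter recovery.  All numeric defaults
# are generator settings chosen to be physically plausible for guanine
# (they are NOT reference quantum-chemistry values).

#' Planar 9-substituted guanine template
#'
#' Standard-geometry guanine base (heavy atoms, ring + exocyclic, z = 0),
#' the template used both to build idealized stacks and as the
#' [idealize_base()] replacement geometry.
#'
#' @param base_type Currently `"G"`.
#' @return A `chromophore_site` with `site_id = 0`.
#' @export
guanine_template <- function(base_type = "G") {
  if (base_type != "G") stop("only a guanine template is shipped")
  xy <- rbind(
    N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
    C5 = c(0.071, 2.833),  C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
    N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
    N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177))
  atoms <- data.frame(name = rownames(xy),
                      element = substr(rownames(xy), 1, 1),
                      x = xy[, 1], y = xy[, 2], z = 0)
  chromophore_site(0L, "G0", "G", atoms)
}

#' Generator specification
#'
#' Bundles every knob of the synthetic generator: helical parameters of the
#' idealized stack, monomer LE settings, the distance-dependent CT model and
#' the noise levels of the MD-like perturbations.  The same spec (including
#' `seed`) always reproduces identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_tetrads Number of stacked tetrads (>= 1).
#' @param rise Inter-tetrad rise (Angstrom); scalar or one value per
#'   interface.
#' @param twist Inter-tetrad twist (degrees); scalar or per interface.
#' @param slide Inter-tetrad slide along x (Angstrom); scalar or per
#'   interface.
#' @param radius Distance of each base centre of mass from the helical axis.
#' @param e_la,e_lb Monomer LE energies (eV).
#' @param mu_la,mu_lb Electric transition dipole magnitudes (a.u.,
#'   velocity gauge).
#' @param ang_la,ang_lb In-plane dipole directions (degrees from the
#'   template x axis).
#' @param mag_la,mag_lb Intrinsic magnetic dipole magnitudes (a.u., along
#'   the base normal); default 0 so the excitonic CD is conservative.
#' @param v_lalb Same-site La-Lb mixing used in the true diabatic model
#'   (eV).
#' @param ct_e0 CT energy at reference separation `ct_r0` (eV).
#' @param ct_slope Linear CT energy dependence on the donor-acceptor
#'   centre-of-mass distance (eV per Angstrom, positive: closer stacking
#'   stabilizes CT).
#' @param ct_r0 Reference separation (Angstrom).
#' @param ct_gamma_step Energy stagger between CT orbital pairs (eV).
#' @param lect_v0 LE-CT coupling scale at `ct_r0` (eV).
#' @param lect_decay Exponential decay length of the LE-CT coupling
#'   (Angstrom).
#' @param ctct_same,ctct_opp CT-CT couplings, same and opposite transfer
#'   direction (eV).
#' @param ct_mu CT electric transition dipole magnitude (a.u., along the
#'   donor-to-acceptor axis).
#' @param rise_noise,twist_noise,slide_noise Per-interface Gaussian drift of
#'   the helical parameters in MD-like snapshots.
#' @param pos_noise,rot_noise Per-base rigid jitter (Angstrom, degrees).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_tetrads = 3L, rise = 3.3,
                           twist = 30, slide = 0, radius = 3.9,
                           e_la = 5.30, e_lb = 5.58,
                           mu_la = 1.00, mu_lb = 0.65,
                           ang_la = -35, ang_lb = 55,
                           mag_la = 0, mag_lb = 0,
                           v_lalb = 0.012,
                           ct_e0 = 5.90, ct_slope = 2.0, ct_r0 = 3.4,
                           ct_gamma_step = 0.15,
                           lect_v0 = 0.12, lect_decay = 0.6,
                           ctct_same = 0.05, ctct_opp = 0.03,
                           ct_mu = 0.08,
                           rise_noise = 0.15, twist_noise = 4,
                           slide_noise = 0.25,
                           pos_noise = 0.08, rot_noise = 2) {
  spec <- as.list(environment())
  if (spec$n_tetrads < 1) stop("n_tetrads must be >= 1")
  if (any(c(spec$rise_noise, spec$twist_noise, spec$slide_noise,
            spec$pos_noise, spec$rot_noise) < 0))
    stop("noise levels must be >= 0")
  if (any(spec$rise <= 0)) stop("rise must be positive")
  structure(spec, class = "generator_spec")
}

# evaluate a deterministic function under a seeded, isolated RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# per-interface parameter vector of length n-1
.per_interface <- function(x, n) {
  if (n <= 1) return(numeric(0))
  if (length(x) == 1) rep(x, n - 1)
  else if (length(x) == n - 1) x
  else stop("helical parameter must be scalar or one value per interface")
}

#' Build an idealized tetrad stack
#'
#' Constructs `n_tetrads` planar guanine tetrads related by the spec's
#' rise/twist/slide, each tetrad being four template guanines at `radius`
#' from the axis with their O6 carbonyls pointing inwards (the Hoogsteen
#' arrangement).  Sites are numbered tetrad-major (tetrad t holds sites
#' `4(t-1)+1 ... 4t`), so strand s is the site column `s, s+4, s+8, ...`.
#'
#' @param spec A `generator_spec`.
#' @param jitter Optional list with per-base rigid noise (`pos_noise`,
#'   `rot_noise`), used by [make_md_like_series()]; `NULL` for the ideal
#'   geometry.
#' @return List with `sites` (chromophore sites), `graph`
#'   (`neighbor_graph`, from the construction topology) and `topology`
#'   (tetrads in cyclic Hoogsteen order, strands in stacking order).
#' @export
make_ideal_stack <- function(spec, jitter = NULL) {
  tmpl <- guanine_template()
  xyz0 <- site_coords(tmpl)
  ctr <- tmpl$com
  # orient: COM -> O6 towards -x (the helix axis), then put COM at (radius,0)
  v <- xyz0["O6", ] - ctr
  ang <- atan2(v[2], v[1]) * 180 / pi
  base0 <- sweep(xyz0, 2, ctr) %*% .rot_z(180 - ang)
  base0 <- sweep(base0, 2, c(spec$radius, 0, 0), "+")

  rises <- .per_interface(spec$rise, spec$n_tetrads)
  twists <- .per_interface(spec$twist, spec$n_tetrads)
  slides <- .per_interface(spec$slide, spec$n_tetrads)
  z <- c(0, cumsum(rises)); tw <- c(0, cumsum(twists))
  sl <- c(0, cumsum(slides))

  sites <- list(); sid <- 0L
  tetrads <- list(); n_sites <- 4L * spec$n_tetrads
  for (t in seq_len(spec$n_tetrads)) {
    tet_ids <- integer(4)
    for (k in 0:3) {
      xyz <- base0 %*% .rot_z(90 * k + tw[t])
      xyz <- sweep(xyz, 2, c(sl[t], 0, z[t]), "+")
      if (!is.null(jitter)) {
        xyz <- xyz %*% .rot_z(stats::rnorm(1, 0, jitter$rot_noise))
        xyz <- sweep(xyz, 2, stats::rnorm(3, 0, jitter$pos_noise), "+")
      }
      sid <- sid + 1L
      atoms <- tmpl$atoms
      atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
      sites[[sid]] <- chromophore_site(sid, paste0("G", sid), "G", atoms)
      tet_ids[k + 1L] <- sid
    }
    tetrads[[t]] <- tet_ids
  }
  strands <- lapply(1:4, function(k) seq(k, n_sites, by = 4L))
  topology <- list(tetrads = tetrads, strands = strands)
  graph <- classify_neighbors(sites, topology = topology)
  list(sites = sites, graph = graph, topology = topology)
}

#' Synthetic monomer transition data
#'
#' Builds guanine La/Lb transition data in the template frame: energies and
#' dipole magnitudes/directions from the spec, and atomic transition charges
#' constructed (minimum-norm, exactly) so that they sum to zero and
#' reproduce the requested dipole, `sum_a q_a r_a = mu`.
#'
#' @param spec A `generator_spec`.
#' @return A `monomer_transition_data` in the [guanine_template()] frame.
#' @export
make_monomer_data <- function(spec) {
  tmpl <- guanine_template()
  xyz <- .ang2bohr(site_coords(tmpl))   # charges reproduce mu in a.u.
  A <- rbind(1, t(xyz))                 # 4 x n constraint matrix
  # min-norm q with A q = (0, mu): pseudoinverse handles the planar template
  # (the z-moment row is identically zero and mu_z = 0)
  sv <- svd(A)
  keep <- sv$d > 1e-10 * sv$d[1]
  mk <- function(energy, mu_mag, ang_deg, mag_mag) {
    mu <- mu_mag * c(cos(ang_deg * pi / 180), sin(ang_deg * pi / 180), 0)
    b <- c(0, mu)
    q <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                      ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
    names(q) <- tmpl$atoms$name
    list(energy = energy, elec_tdip = mu, mag_tdip = c(0, 0, mag_mag),
         charges = q)
  }
  monomer_transition_data(
    "G", tmpl$atoms$name,
    list(La = mk(spec$e_la, spec$mu_la, spec$ang_la, spec$mag_la),
         Lb = mk(spec$e_lb, spec$mu_lb, spec$ang_lb, spec$mag_lb)),
    gauge = "velocity")
}

#' Attach synthetic monomer data to every site
#'
#' @param sites List of `chromophore_site`.
#' @param spec A `generator_spec`.
#' @return Sites with rotated `monomer_data`.
#' @export
attach_all_monomer_data <- function(sites, spec) {
  mono <- make_monomer_data(spec)
  tmpl <- guanine_template()
  lapply(sites, attach_monomer_data, monomer = mono, template = tmpl)
}

#' True diabatic model of a nearest-neighbour pair
#'
#' The generator's ground truth for one pair: a labeled symmetric
#' Hamiltonian over the pair basis (4 LE states, `2 * n_ct` CT states) plus
#' per-state transition properties.  LE energies and the same-site La-Lb
#' mixing are the monomer settings; cross-site LE-LE couplings are computed
#' from the attached transition charges; CT energies follow the linear
#' distance model `e_CT(R) = ct_e0 + ct_slope (R - ct_r0)` (staggered by
#' orbital pair); LE-CT couplings decay exponentially with separation, with
#' deterministic sign/scale patterns over (alpha, gamma, hole/electron
#' side).
#'
#' @param spec A `generator_spec`.
#' @param site_m,site_n `chromophore_site` with attached `monomer_data`.
#' @param n_ct_per_direction CT states per transfer direction.
#' @return List with `labels`, `H` (eV), `elec_tdip`, `mag_tdip` (matrices).
#' @export
make_pair_h_true <- function(spec, site_m, site_n,
                             n_ct_per_direction = 2L) {
  m <- site_m$site_id; n <- site_n$site_id
  if (is.null(site_m$monomer_data) || is.null(site_n$monomer_data))
    stop("sites need attached monomer_data")
  labels <- c(le_label(m, "La"), le_label(m, "Lb"),
              le_label(n, "La"), le_label(n, "Lb"))
  if (n_ct_per_direction > 0)
    labels <- c(labels,
                vapply(seq_len(n_ct_per_direction), function(g)
                  ct_label(m, n, g), ""),
                vapply(seq_len(n_ct_per_direction), function(g)
                  ct_label(n, m, g), ""))
  nb <- length(labels)
  H <- matrix(0, nb, nb, dimnames = list(labels, labels))
  mu <- matrix(0, nb, 3); mg <- matrix(0, nb, 3)
  R <- com_distance(site_m, site_n)

  put_le <- function(idx, site, alpha) {
    st <- site$monomer_data$states[[alpha]]
    H[idx, idx] <<- st$energy
    mu[idx, ] <<- st$elec_tdip
    mg[idx, ] <<- st$mag_tdip
  }
  put_le(1, site_m, "La"); put_le(2, site_m, "Lb")
  put_le(3, site_n, "La"); put_le(4, site_n, "Lb")
  H[1, 2] <- H[2, 1] <- spec$v_lalb
  H[3, 4] <- H[4, 3] <- spec$v_lalb
  # cross-site LE-LE Coulombic couplings from transition charges
  for (a in 1:2) for (b in 3:4) {
    alpha <- c("La", "Lb")[a]; beta <- c("La", "Lb")[b - 2]
    v <- transition_charge_coupling(
      site_m$monomer_data$states[[alpha]]$charges, site_coords(site_m),
      site_n$monomer_data$states[[beta]]$charges, site_coords(site_n))
    H[a, b] <- H[b, a] <- v
  }
  if (n_ct_per_direction > 0) {
    gam_scale <- c(1, 0.8, -0.5, 0.4, -0.3, 0.25)
    alp_scale <- c(La = 1, Lb = -0.6)
    vle <- spec$lect_v0 * exp(-(R - spec$ct_r0) / spec$lect_decay)
    dirs <- list(list(off = 4L, donor_le = 1:2, acceptor_le = 3:4,
                      axis = .unit3(site_n$com - site_m$com)),
                 list(off = 4L + n_ct_per_direction, donor_le = 3:4,
                      acceptor_le = 1:2,
                      axis = .unit3(site_m$com - site_n$com)))
    for (d in dirs) {
      for (g in seq_len(n_ct_per_direction)) {
        ic <- d$off + g
        H[ic, ic] <- spec$ct_e0 + spec$ct_slope * (R - spec$ct_r0) +
          spec$ct_gamma_step * (g - 1)
        mu[ic, ] <- spec$ct_mu * d$axis
        # hole-side couplings (LE on the donor)
        for (a in d$donor_le) {
          alpha <- c("La", "Lb")[(a - 1) %% 2 + 1]
          v <- vle * alp_scale[[alpha]] * gam_scale[g]
          H[a, ic] <- H[ic, a] <- v
        }
        # electron-side couplings (LE on the acceptor), reduced
        for (a in d$acceptor_le) {
          alpha <- c("La", "Lb")[(a - 1) %% 2 + 1]
          v <- 0.7 * vle * alp_scale[[alpha]] * gam_scale[g]
          H[a, ic] <- H[ic, a] <- v
        }
        # CT-CT same direction
        for (g2 in seq_len(n_ct_per_direction)) if (g2 > g) {
          H[d$off + g, d$off + g2] <- H[d$off + g2, d$off + g] <-
            spec$ctct_same
        }
      }
    }
    # CT-CT opposite direction
    for (g in seq_len(n_ct_per_direction))
      for (g2 in seq_len(n_ct_per_direction)) {
        i1 <- 4L + g; i2 <- 4L + n_ct_per_direction + g2
        H[i1, i2] <- H[i2, i1] <- spec$ctct_opp
      }
  }
  list(labels = labels, H = H, elec_tdip = mu, mag_tdip = mg)
}

#' Emit consistent adiabatic data from a known diabatic model
#'
#' Diagonalizes a true diabatic Hamiltonian and emits exactly the data an
#' upstream electronic-structure step would provide: the reference-state
#' overlap matrix S (rows of the eigenvector matrix restricted to the kept
#' adiabatic states), the adiabatic energies, and the adiabatic transition
#' properties.  Untruncated, fragment diabatization of this output recovers
#' the true model to machine precision.
#'
#' @param h_true List from [make_pair_h_true()] (or any `labels`/`H`/
#'   `elec_tdip`/`mag_tdip` list with symmetric `H`).
#' @param n_adiabatic Number of (lowest) adiabatic states kept; defaults to
#'   the full dimension.
#' @param sc_id Identifier for the emitted `adiabatic_set`.
#' @return List with `ref` (`reference_overlap`) and `adia`
#'   (`adiabatic_set`).
#' @export
make_consistent_sc <- function(h_true, n_adiabatic = ncol(h_true$H),
                               sc_id = "sc") {
  H <- h_true$H
  if (max(abs(H - t(H))) > 1e-10) stop("true Hamiltonian must be symmetric")
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))
  vals <- eig$values[ord]
  C <- eig$vectors[, ord, drop = FALSE]    # rows: diabatic, cols: adiabatic
  keep <- seq_len(n_adiabatic)
  S <- C[, keep, drop = FALSE]
  elec <- crossprod(C, h_true$elec_tdip)[keep, , drop = FALSE]
  mag <- crossprod(C, h_true$mag_tdip)[keep, , drop = FALSE]
  # under truncation the caller must also restrict the reference set before
  # diabatizing; until then the overlap block is returned unclassed
  ref <- if (length(h_true$labels) <= n_adiabatic)
    reference_overlap(h_true$labels, S)
  else {
    rownames(S) <- h_true$labels
    list(labels = h_true$labels, S = S)
  }
  list(ref = ref,
       adia = adiabatic_set(sc_id, vals[keep], elec, mag,
                            gauge = "velocity"))
}

#' True LE-only model of a strand or tetrad
#'
#' Ground truth for the intra-molecular parametrization on a larger
#' supramolecular complex: LE states of the member sites with the monomer
#' energies, same-site La-Lb mixing and Coulombic cross-site couplings.
#'
#' @param spec A `generator_spec`.
#' @param sites Member `chromophore_site` list (with `monomer_data`).
#' @return List with `labels`, `H`, `elec_tdip`, `mag_tdip`.
#' @export
make_le_sc_h_true <- function(spec, sites) {
  ns <- length(sites)
  labels <- as.character(vapply(sites, function(s)
    c(le_label(s$site_id, "La"), le_label(s$site_id, "Lb")),
    character(2)))
  nb <- length(labels)
  H <- matrix(0, nb, nb, dimnames = list(labels, labels))
  mu <- matrix(0, nb, 3); mg <- matrix(0, nb, 3)
  for (i in seq_len(ns)) {
    for (a in 1:2) {
      alpha <- c("La", "Lb")[a]
      idx <- 2 * (i - 1) + a
      st <- sites[[i]]$monomer_data$states[[alpha]]
      H[idx, idx] <- st$energy
      mu[idx, ] <- st$elec_tdip
      mg[idx, ] <- st$mag_tdip
    }
    H[2 * i - 1, 2 * i] <- H[2 * i, 2 * i - 1] <- spec$v_lalb
  }
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
    for (a in 1:2) for (b in 1:2) {
      alpha <- c("La", "Lb")[a]; beta <- c("La", "Lb")[b]
      v <- transition_charge_coupling(
        sites[[i]]$monomer_data$states[[alpha]]$charges,
        site_coords(sites[[i]]),
        sites[[j]]$monomer_data$states[[beta]]$charges,
        site_coords(sites[[j]]))
      H[2 * (i - 1) + a, 2 * (j - 1) + b] <- v
      H[2 * (j - 1) + b, 2 * (i - 1) + a] <- v
    }
  list(labels = labels, H = H, elec_tdip = mu, mag_tdip = mg)
}

#' Full synthetic parametrization for a structure
#'
#' Generates the complete interchange payload for one structure: guanine
#' monomer data, one pair supramolecular complex per nearest-neighbour pair
#' (projected, like the upstream step, onto `n_pair_adiabatic` states or the
#' full pair dimension if smaller) and LE-only strand complexes for the
#' intra parametrization.
#'
#' @param stack Output of [make_ideal_stack()] (sites/graph/topology).
#' @param spec A `generator_spec`.
#' @param n_ct_per_direction CT states per direction for the pair blocks.
#' @return List with `monomers`, `scs` (as written by
#'   [write_parametrization_json()]) and `sites` (with attached monomer
#'   data).
#' @export
make_parametrization <- function(stack, spec,
                                 n_ct_per_direction = frdex_config()$n_ct_per_direction) {
  sites <- attach_all_monomer_data(stack$sites, spec)
  byid <- setNames(sites, vapply(sites, function(s)
    as.character(s$site_id), ""))
  scs <- list()
  gp <- stack$graph$pairs
  for (r in seq_len(nrow(gp))) {
    sm <- byid[[as.character(gp$i[r])]]
    sn <- byid[[as.character(gp$j[r])]]
    ht <- make_pair_h_true(spec, sm, sn, n_ct_per_direction)
    sc <- make_consistent_sc(ht, sc_id = sprintf("pair-%d-%d",
                                                 gp$i[r], gp$j[r]))
    sc$kind <- "pair"
    scs[[length(scs) + 1L]] <- sc
  }
  for (s in stack$topology$strands) {
    member <- lapply(s, function(i) byid[[as.character(i)]])
    ht <- make_le_sc_h_true(spec, member)
    sc <- make_consistent_sc(ht, sc_id = paste0("strand-",
                                                paste(s, collapse = "-")))
    sc$kind <- "strand"
    scs[[length(scs) + 1L]] <- sc
  }
  list(monomers = list(G = make_monomer_data(spec)), scs = scs,
       sites = sites)
}

#' MD-like snapshot series
#'
#' Produces `n_snapshots` perturbed copies of the ideal stack: the
#' per-interface helical parameters drift (Gaussian, `rise_noise` etc.) and
#' each base receives a small rigid jitter, so interface overlap areas vary
#' across the series the way tetrad stacking breathes in an MD trajectory.
#' Bitwise reproducible from `spec$seed`.
#'
#' @param spec A `generator_spec`.
#' @param n_snapshots Number of structures (>= 1).
#' @return List of stacks (each as from [make_ideal_stack()]).
#' @export
make_md_like_series <- function(spec, n_snapshots) {
  if (n_snapshots < 1) stop("n_snapshots must be >= 1")
  .with_seed(spec$seed, {
    lapply(seq_len(n_snapshots), function(i) {
      sp <- spec
      ni <- spec$n_tetrads - 1L
      if (ni > 0) {
        sp$rise <- pmax(2.8, .per_interface(spec$rise, spec$n_tetrads) +
                          stats::rnorm(ni, 0, spec$rise_noise))
        sp$twist <- .per_interface(spec$twist, spec$n_tetrads) +
          stats::rnorm(ni, 0, spec$twist_noise)
        sp$slide <- .per_interface(spec$slide, spec$n_tetrads) +
          stats::rnorm(ni, 0, spec$slide_noise)
      }
      jit <- if (spec$pos_noise > 0 || spec$rot_noise > 0)
        list(pos_noise = spec$pos_noise, rot_noise = spec$rot_noise)
      else NULL
      make_ideal_stack(sp, jitter = jit)
    })
  })
}
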