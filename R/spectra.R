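# Diagonalization of the excitonic Hamiltonian, origin-independent
# velocity-gauge rotational strengths, oscillator strengths, and Gaussian
# broadening of stick spectra onto a wavelength grid.

#' Diagonalize an excitonic Hamiltonian
#'
#' Standard symmetric eigenproblem with deterministic conventions: energies
#' ascending, eigenvector phase fixed so the largest-magnitude coefficient is
#' positive (ties towards the lowest basis index), degenerate states ordered
#' by the basis index of their largest coefficient.
#'
#' @param ham An `exciton_hamiltonian` (or plain symmetric matrix).
#' @param compute_strengths If `TRUE` (default) and `ham` carries positions
#'   and dipoles, per-state rotational and oscillator strengths are attached
#'   via [rotational_strengths()] and [oscillator_strengths()].
#' @return Object of class `exciton_states`: list with `energies` (eV),
#'   `coefficients` (basis x states), `R` (1e-40 cgs), `f`, `basis`,
#'   `positions`, `elec_tdip`, `mag_tdip`.
#' @export
diagonalize <- function(ham, compute_strengths = TRUE) {
  H <- if (inherits(ham, "exciton_hamiltonian")) ham$H else as.matrix(ham)
  if (max(abs(H - t(H))) > 1e-8) stop("Hamiltonian must be symmetric")
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))       # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # phase fix + stable ordering of exact degeneracies
  lead <- integer(ncol(vecs))
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]) - seq_len(nrow(vecs)) * 1e-15)
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
    lead[k] <- i
  }
  ord2 <- order(vals, lead)
  vals <- vals[ord2]; vecs <- vecs[, ord2, drop = FALSE]
  st <- structure(list(energies = vals, coefficients = vecs,
                       R = NULL, f = NULL,
                       basis = if (inherits(ham, "exciton_hamiltonian"))
                         ham$basis else NULL,
                       positions = if (inherits(ham, "exciton_hamiltonian"))
                         ham$positions else NULL,
                       elec_tdip = if (inherits(ham, "exciton_hamiltonian"))
                         ham$elec_tdip else NULL,
                       mag_tdip = if (inherits(ham, "exciton_hamiltonian"))
                         ham$mag_tdip else NULL),
                  class = "exciton_states")
  if (compute_strengths && !is.null(st$positions)) {
    st$R <- rotational_strengths(st)
    st$f <- oscillator_strengths(st)
  }
  st
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("<exciton_states: %d states, E in [%.3f, %.3f] eV%s>\n",
              length(x$energies), min(x$energies), max(x$energies),
              if (!is.null(x$R)) sprintf(", sum R = %.3e", sum(x$R)) else ""))
  invisible(x)
}

#' Origin-independent velocity-gauge rotational strengths
#'
#' For each excitonic state k the rotational strength combines the intrinsic
#' site contributions `sum_i C_ik^2 (mu_i . m_i)` and the extrinsic
#' inter-site terms `(1/2c) C_ik C_jk (r_i - r_j) . (mu_i x mu_j)` arising
#' from the positional part of the magnetic transition moment,
#' `m_i^ext = (1/2c) r_i x mu_i` (atomic units, velocity-gauge electric
#' dipoles).  Because the extrinsic prefactor is state independent, the
#' result is exactly invariant under rigid translations and rotations of the
#' whole system, and the trace sum rule holds exactly: `sum_k R_k` equals
#' the sum of the intrinsic basis-state terms (zero when intrinsic magnetic
#' moments vanish).
#'
#' @param states An `exciton_states` carrying basis positions and dipoles.
#' @param unit `"cgs"` (default, 1e-40 cgs) or `"au"`.
#' @return Numeric vector of per-state rotational strengths.
#' @export
rotational_strengths <- function(states, unit = c("cgs", "au")) {
  unit <- match.arg(unit)
  if (is.null(states$positions) || is.null(states$elec_tdip))
    stop("basis positions and velocity-gauge electric dipoles are required")
  C <- states$coefficients
  mu <- states$elec_tdip
  m <- states$mag_tdip
  if (is.null(m)) m <- matrix(0, nrow(mu), 3)
  r <- .ang2bohr(states$positions)
  # extrinsic magnetic moment (1/2c) r x mu per basis state
  pref <- 1 / (2 * .frdex_const$c_au)
  mex <- m + pref * cbind(r[, 2] * mu[, 3] - r[, 3] * mu[, 2],
                          r[, 3] * mu[, 1] - r[, 1] * mu[, 3],
                          r[, 1] * mu[, 2] - r[, 2] * mu[, 1])
  M <- crossprod(C, mu)    # state electric dipoles
  N <- crossprod(C, mex)   # state magnetic moments
  R_au <- rowSums(M * N)
  if (unit == "au") R_au else R_au * .frdex_const$rot_au_cgs
}

#' Oscillator strengths
#'
#' `f_k = (2/3) E_k |sum_i C_ik mu_i|^2` in atomic units (E in hartree).
#'
#' @param states An `exciton_states` with basis electric dipoles.
#' @return Numeric vector of per-state oscillator strengths.
#' @export
oscillator_strengths <- function(states) {
  if (is.null(states$elec_tdip))
    stop("basis electric transition dipoles are required")
  M <- crossprod(states$coefficients, states$elec_tdip)
  (2 / 3) * (states$energies / .frdex_const$hartree_ev) * rowSums(M^2)
}

#' Spectrum curve container
#'
#' @param wavelength Strictly monotone wavelength grid (nm).
#' @param intensity Intensities (signed for CD).
#' @param shift_applied Energy shift that was applied to the sticks (eV).
#' @param sigma Gaussian broadening standard deviation (eV).
#' @param normalization List with `scale` and `reference` description.
#' @param meta Free-form metadata list.
#' @return Object of class `spectrum_curve` with mirror `energy` grid (eV).
#' @export
spectrum_curve <- function(wavelength, intensity, shift_applied, sigma,
                           normalization = list(scale = 1,
                                                reference = "none"),
                           meta = list()) {
  if (length(wavelength) != length(intensity))
    stop("grid and intensity lengths differ")
  d <- diff(wavelength)
  if (!(all(d > 0) || all(d < 0))) stop("grid must be strictly monotone")
  structure(list(wavelength = wavelength, energy = .nm2ev(wavelength),
                 intensity = intensity, shift_applied = shift_applied,
                 sigma = sigma, normalization = normalization, meta = meta),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf(
    "<spectrum_curve: %d points, %.0f-%.0f nm, shift %.2f eV, sigma %.2f eV, scale %.3g>\n",
    length(x$wavelength), min(x$wavelength), max(x$wavelength),
    x$shift_applied, x$sigma, x$normalization$scale))
  invisible(x)
}

#' Broaden a stick spectrum into a curve
#'
#' Each stick (energy, intensity) becomes a Gaussian in the energy domain,
#' centred at the stick energy plus the empirical `shift` and of standard
#' deviation `sigma`; amplitudes are area normalized
#' (`value / (sigma sqrt(2 pi))`), so halving sigma doubles an isolated
#' peak.  The curve is evaluated on a wavelength grid (default 220-340 nm at
#' 0.5 nm) through the energy mirror of each grid point.
#'
#' @param sticks Data frame with columns `energy` (eV) and `value`
#'   (rotational strength for CD, oscillator strength for absorption).
#' @param sigma Gaussian standard deviation (eV), > 0.
#' @param shift Rigid energy shift applied to the sticks (eV); the default
#'   -0.85 eV aligns computed guanine spectra with experiment.
#' @param grid_nm Wavelength grid (nm).
#' @param meta Metadata stored on the curve.
#' @return A `spectrum_curve`.
#' @export
stick_to_curve <- function(sticks, sigma = frdex_config()$sigma_ev,
                           shift = frdex_config()$shift_ev,
                           grid_nm = frdex_config()$grid_nm,
                           meta = list()) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!nrow(sticks)) {
    warning("empty stick list: returning a zero curve")
    return(spectrum_curve(grid_nm, rep(0, length(grid_nm)), shift, sigma,
                          meta = meta))
  }
  e_grid <- .nm2ev(grid_nm)
  centers <- sticks$energy + shift
  amp <- sticks$value / (sigma * sqrt(2 * pi))
  inten <- vapply(e_grid, function(e)
    sum(amp * exp(-((e - centers)^2) / (2 * sigma^2))), numeric(1))
  spectrum_curve(grid_nm, inten, shift, sigma, meta = meta)
}

#' Stick table of an excitonic calculation
#'
#' @param states An `exciton_states` with strengths attached.
#' @param value `"R"` (CD) or `"f"` (absorption).
#' @return Data frame with `state`, `energy` (eV), `wavelength` (nm, of the
#'   unshifted energy), `R`, `f`, and `value` (the selected intensity).
#' @export
stick_table <- function(states, value = c("R", "f")) {
  value <- match.arg(value)
  v <- states[[value]]
  if (is.null(v)) stop("states carry no ", value, " values")
  data.frame(state = seq_along(states$energies),
             energy = states$energies,
             wavelength = .ev2nm(states$energies),
             R = states$R, f = states$f,
             value = v)
}

#' Average spectra over snapshots
#'
#' Pointwise arithmetic mean of curves computed on identical grids (e.g. the
#' per-snapshot spectra of an MD ensemble).
#'
#' @param curves List of `spectrum_curve` with identical grids, shifts and
#'   sigmas.
#' @return A `spectrum_curve`; `meta$n_averaged` records the count and
#'   `meta$members` any `meta$id` of the inputs.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("no curves to average")
  g <- curves[[1]]$wavelength
  for (cv in curves)
    if (!isTRUE(all.equal(cv$wavelength, g, tolerance = 1e-12)))
      stop("curves must share an identical grid")
  inten <- Reduce(`+`, lapply(curves, function(cv) cv$intensity)) /
    length(curves)
  ids <- unlist(lapply(curves, function(cv) cv$meta$id %||% NA_character_))
  spectrum_curve(g, inten, curves[[1]]$shift_applied, curves[[1]]$sigma,
                 meta = list(n_averaged = length(curves),
                             members = ids))
}

#' Normalize a curve to a reference peak
#'
#' Scales a curve so that a selected extremum matches a reference value
#' (computed spectra are in arbitrary units; comparison with experiment
#' normalizes to the lowest-energy peak).  The applied scale factor is
#' stored so sibling curves can be scaled by the same value rather than
#' re-normalized.
#'
#' @param curve A `spectrum_curve`.
#' @param reference Target value for the selected peak (default 1).
#' @param which_peak `"lowest_energy"` (default: the extremum of largest
#'   wavelength among those reaching at least `min_frac` of the global
#'   absolute maximum) or `"global"`.
#' @param scale If given, the curve is multiplied by this factor and no peak
#'   search is performed (reuse of a sibling's factor).
#' @param min_frac Relative prominence threshold for peak candidates.
#' @return The scaled `spectrum_curve`; `normalization$scale` holds the
#'   factor.
#' @export
normalize_to_peak <- function(curve, reference = 1,
                              which_peak = c("lowest_energy", "global"),
                              scale = NULL, min_frac = 0.05) {
  which_peak <- match.arg(which_peak)
  if (is.null(scale)) {
    y <- curve$intensity
    if (max(abs(y)) < 1e-300) stop("cannot normalize a flat curve")
    n <- length(y)
    ay <- abs(y)
    is_ext <- c(FALSE, diff(sign(diff(ay))) < 0, FALSE) |
      seq_len(n) %in% c(which.max(ay))
    cand <- which(is_ext & ay >= min_frac * max(ay))
    if (!length(cand)) cand <- which.max(ay)
    pick <- if (which_peak == "global") cand[which.max(ay[cand])]
            else cand[which.max(curve$wavelength[cand])]
    scale <- reference / y[pick]
  }
  curve$intensity <- curve$intensity * scale
  curve$normalization <- list(scale = scale,
                              reference = sprintf("peak -> %g", reference))
  curve
}

#' Write a spectrum curve (and metadata) to disk
#'
#' Two-column TSV (`wavelength_nm`, `intensity`) plus a JSON sidecar with
#' shift, sigma and normalization metadata.
#'
#' @param curve A `spectrum_curve`.
#' @param path TSV output path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(curve, path) {
  write.table(data.frame(wavelength_nm = curve$wavelength,
                         intensity = curve$intensity),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(shift_applied = curve$shift_applied,
                            sigma = curve$sigma,
                            normalization = curve$normalization,
                            meta = curve$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
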