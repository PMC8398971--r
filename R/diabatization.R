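# Fragment diabatization: from supramolecular-complex (SC) adiabatic data to
# diabatic local-excitation (LE) / charge-transfer (CT) energies, couplings
# and transition properties, via Loewdin symmetric orthogonalization of the
# reference-state overlap matrix.

# ---- basis-state labels ------------------------------------------------------
# LE label: "LE:<site>:<alpha>"   (alpha in La, Lb)
# CT label: "CT:<donor>><acceptor>:<gamma>"

#' Basis-state labels
#'
#' Helpers creating and parsing the canonical basis-state labels used across
#' the package: `"LE:<site>:<alpha>"` for a local excitation and
#' `"CT:<donor>><acceptor>:<gamma>"` for a charge-transfer state (electron
#' moved from donor to acceptor, orbital-pair index gamma).
#'
#' @param site,donor,acceptor Site ids (integers).
#' @param alpha LE label, `"La"` or `"Lb"`.
#' @param gamma CT orbital-pair index (integer).
#' @return `le_label`/`ct_label`: character labels. `parse_labels`: data
#'   frame with columns `label`, `kind`, `site`, `alpha`, `donor`,
#'   `acceptor`, `gamma`.
#' @export
le_label <- function(site, alpha) sprintf("LE:%d:%s", as.integer(site), alpha)

#' @rdname le_label
#' @export
ct_label <- function(donor, acceptor, gamma)
  sprintf("CT:%d>%d:%d", as.integer(donor), as.integer(acceptor),
          as.integer(gamma))

#' @rdname le_label
#' @param labels Character vector of labels.
#' @export
parse_labels <- function(labels) {
  out <- data.frame(label = labels, kind = NA_character_,
                    site = NA_integer_, alpha = NA_character_,
                    donor = NA_integer_, acceptor = NA_integer_,
                    gamma = NA_integer_)
  le <- grepl("^LE:", labels)
  ctm <- grepl("^CT:", labels)
  if (any(!le & !ctm)) stop("malformed basis labels")
  if (any(le)) {
    p <- do.call(rbind, strsplit(labels[le], ":", fixed = TRUE))
    out$kind[le] <- "LE"
    out$site[le] <- as.integer(p[, 2]); out$alpha[le] <- p[, 3]
  }
  if (any(ctm)) {
    p <- do.call(rbind, strsplit(labels[ctm], ":", fixed = TRUE))
    da <- do.call(rbind, strsplit(p[, 2], ">", fixed = TRUE))
    out$kind[ctm] <- "CT"
    out$donor[ctm] <- as.integer(da[, 1])
    out$acceptor[ctm] <- as.integer(da[, 2])
    out$gamma[ctm] <- as.integer(p[, 3])
  }
  out
}

# ---- containers --------------------------------------------------------------

#' Reference-state overlap matrix
#'
#' The overlap S of the fragment reference states (rows; LE and CT labels)
#' with the adiabatic states of the supramolecular complex (columns).
#'
#' @param labels Character vector of reference-state labels ([le_label()],
#'   [ct_label()]).
#' @param S Numeric matrix, `length(labels)` x N_adiabatic.
#' @return Object of class `reference_overlap`.
#' @export
reference_overlap <- function(labels, S) {
  S <- as.matrix(S)
  if (length(labels) != nrow(S))
    stop("one label per row of S is required")
  if (nrow(S) > ncol(S))
    stop("more reference states than adiabatic states (N_ref > N_adiabatic)")
  rownames(S) <- labels
  structure(list(labels = labels, S = S), class = "reference_overlap")
}

#' Adiabatic data of a supramolecular complex
#'
#' @param sc_id Identifier string.
#' @param energies Adiabatic energies, eV, ascending.
#' @param elec_tdip N x 3 electric transition dipoles (a.u.).
#' @param mag_tdip N x 3 magnetic transition dipoles (a.u.).
#' @param gauge `"velocity"` (default) or `"length"` flag for `elec_tdip`.
#' @return Object of class `adiabatic_set`.
#' @export
adiabatic_set <- function(sc_id, energies, elec_tdip, mag_tdip,
                          gauge = "velocity") {
  n <- length(energies)
  if (is.unsorted(energies)) stop("adiabatic energies must be ascending")
  elec_tdip <- as.matrix(elec_tdip); mag_tdip <- as.matrix(mag_tdip)
  if (nrow(elec_tdip) != n || nrow(mag_tdip) != n)
    stop("one property vector per adiabatic state is required")
  structure(list(sc_id = sc_id, n_adiabatic = n, energies = energies,
                 elec_tdip = elec_tdip, mag_tdip = mag_tdip, gauge = gauge),
            class = "adiabatic_set")
}

# ---- core operations ---------------------------------------------------------

#' Fix arbitrary adiabatic phases
#'
#' Adiabatic states (and upstream reference states) carry an arbitrary sign.
#' Each adiabatic column of S is flipped so that its largest-magnitude
#' overlap entry is positive; exact magnitude ties are resolved in favour of
#' the lowest reference index.  Deterministic, and gauge-invariant
#' quantities (the diabatic Hamiltonian) do not depend on the incoming
#' signs after this normalization is applied consistently to S and the
#' adiabatic properties.
#'
#' @param ref A `reference_overlap`.
#' @return A `reference_overlap` with fixed column signs, carrying the
#'   applied signs as attribute `"col_signs"`.
#' @export
fix_phases <- function(ref) {
  S <- ref$S
  signs <- numeric(ncol(S))
  for (j in seq_len(ncol(S))) {
    k <- which.max(abs(S[, j]) - seq_len(nrow(S)) * 1e-15) # tie -> lowest row
    signs[j] <- if (S[k, j] < 0) -1 else 1
  }
  out <- reference_overlap(ref$labels, sweep(S, 2, signs, "*"))
  attr(out, "col_signs") <- signs
  out
}

#' Loewdin (symmetric) diabatizing transform
#'
#' Computes `D = t(S) (S t(S))^(-1/2)`, the transformation from SC adiabatic
#' states to diabatic states; `D` has orthonormal columns and is the closest
#' matrix with orthonormal columns to `t(S)` in Frobenius norm, so the
#' diabatic states resemble the reference states as much as an orthonormal
#' set can.
#'
#' @param ref A `reference_overlap` (or plain matrix S).
#' @param sv_threshold Smallest singular value of S accepted before the
#'   projection is declared rank deficient.
#' @return N_adiabatic x N_ref matrix `D` with `t(D) %*% D = I`.
#' @export
lowdin_transform <- function(ref, sv_threshold = frdex_config()$sv_threshold) {
  S <- if (inherits(ref, "reference_overlap")) ref$S else as.matrix(ref)
  sv <- svd(S)
  if (min(sv$d) < sv_threshold) {
    worst <- which.max(abs(sv$u[, which.min(sv$d)]))  # largest |u| entry
    lab <- if (!is.null(rownames(S))) rownames(S)[worst] else
      paste("reference state", worst)
    stop(sprintf(paste0("rank-deficient reference projection: smallest ",
                        "singular value %.3e < %.1e (dominant reference ",
                        "state: %s)"), min(sv$d), sv_threshold, lab))
  }
  # S = U d V^T  =>  t(S)(S t(S))^{-1/2} = V t(U)
  D <- sv$v %*% t(sv$u)
  colnames(D) <- rownames(S)
  D
}

#' Diabatic Hamiltonian
#'
#' Rotates the diagonal matrix of SC adiabatic energies into the diabatic
#' basis: `H_d = t(D) diag(E) D`.  Diagonal entries are diabatic LE/CT
#' energies, off-diagonal entries the electronic couplings.
#'
#' @param D Transform from [lowdin_transform()] (N_adiabatic x N_ref).
#' @param energies Adiabatic energies (length N_adiabatic), eV.
#' @return Symmetric N_ref x N_ref matrix, eV.
#' @export
diabatic_hamiltonian <- function(D, energies) {
  if (length(energies) != nrow(D))
    stop("length(energies) must equal nrow(D)")
  H <- crossprod(D, D * energies)
  H <- (H + t(H)) / 2
  dimnames(H) <- list(colnames(D), colnames(D))
  H
}

#' Transform adiabatic properties to the diabatic basis
#'
#' Applies the diabatizing transform to per-adiabatic-state property vectors
#' (electric or magnetic transition dipoles): diabatic property i is
#' `sum_a D[a, i] * property[a, ]`.
#'
#' @param D N_adiabatic x N_ref transform.
#' @param props N_adiabatic x k matrix (one property vector per state).
#' @return N_ref x k matrix, rownames = diabatic labels.
#' @export
transform_properties <- function(D, props) {
  props <- as.matrix(props)
  if (nrow(props) != nrow(D))
    stop("one property vector per adiabatic state is required")
  out <- crossprod(D, props)
  rownames(out) <- colnames(D)
  out
}

#' Full diabatization of one supramolecular complex
#'
#' Convenience wrapper: fixes phases, forms the Loewdin transform, the
#' diabatic Hamiltonian and the diabatic transition properties, and records
#' per-reference-state completeness (row norms of S, the fraction of each
#' reference state recovered inside the adiabatic space).
#'
#' @param ref A `reference_overlap`.
#' @param adia An `adiabatic_set`.
#' @param sv_threshold Passed to [lowdin_transform()].
#' @param completeness_warn Row-norm level below which a warning is issued.
#' @return Object of class `diabatization_result`: list with `labels`, `D`,
#'   `H_d` (eV), `elec_tdip`, `mag_tdip` (a.u.), `completeness`, `gauge`.
#' @export
diabatize_sc <- function(ref, adia,
                         sv_threshold = frdex_config()$sv_threshold,
                         completeness_warn = frdex_config()$completeness_warn) {
  ref <- fix_phases(ref)
  if (ncol(ref$S) != adia$n_adiabatic)
    stop("overlap matrix and adiabatic set disagree on N_adiabatic")
  comp <- sqrt(rowSums(ref$S^2))
  names(comp) <- ref$labels
  low <- comp < completeness_warn
  if (any(low))
    warning("low reference-state completeness (projection far from ",
            "complete) for: ",
            paste(sprintf("%s (%.2f)", ref$labels[low], comp[low]),
                  collapse = ", "))
  signs <- attr(ref, "col_signs")
  D <- lowdin_transform(ref, sv_threshold)
  structure(list(labels = ref$labels, D = D,
                 H_d = diabatic_hamiltonian(D, adia$energies),
                 elec_tdip = transform_properties(D, adia$elec_tdip * signs),
                 mag_tdip = transform_properties(D, adia$mag_tdip * signs),
                 completeness = comp, gauge = adia$gauge,
                 sc_id = adia$sc_id),
            class = "diabatization_result")
}

#' @export
print.diabatization_result <- function(x, ...) {
  cat(sprintf("<diabatization_result %s: %d diabatic states from %d adiabatic; min completeness %.3f>\n",
              x$sc_id, length(x$labels), nrow(x$D), min(x$completeness)))
  invisible(x)
}

# ---- pair blocks and intra parameters ---------------------------------------

#' Diabatize a nearest-neighbour pair
#'
#' Produces the pair block of the inter-molecular Hamiltonian: the diabatized
#' LE and CT energies and every coupling class between the two sites
#' (LE-LE cross-site, LE-CT hole-side and electron-side, CT-CT same- and
#' opposite-direction), plus diabatic transition dipoles for the CT states.
#'
#' @param ref A `reference_overlap` whose labels contain the two LEs
#'   (La, Lb) of each site and `n_ct_per_direction` CT states per direction
#'   (2 per direction gives the minimal 4-CT-state setting, 6 gives 12).
#' @param adia The matching `adiabatic_set` (pairs are typically projected
#'   onto 40 adiabatic states).
#' @param n_ct_per_direction Expected CT states per transfer direction; 0
#'   allows a CT-free (LE-only) block.
#' @param ... Passed to [diabatize_sc()].
#' @return Object of class `pair_block`: a `diabatization_result` augmented
#'   with `sites` (the two site ids) and `n_ct_per_direction`.
#' @export
build_pair_block <- function(ref, adia,
                             n_ct_per_direction = frdex_config()$n_ct_per_direction,
                             ...) {
  lab <- parse_labels(ref$labels)
  sites <- sort(unique(c(lab$site[lab$kind == "LE"])))
  if (length(sites) != 2L)
    stop("a pair block requires LE labels on exactly 2 sites")
  for (s in sites) for (a in c("La", "Lb"))
    if (!le_label(s, a) %in% ref$labels)
      stop("missing reference label ", le_label(s, a))
  for (dd in list(c(sites[1], sites[2]), c(sites[2], sites[1]))) {
    got <- sum(lab$kind == "CT" & lab$donor == dd[1] & lab$acceptor == dd[2],
               na.rm = TRUE)
    if (got != n_ct_per_direction)
      stop(sprintf("expected %d CT reference states for %d->%d, found %d",
                   n_ct_per_direction, dd[1], dd[2], got))
  }
  res <- diabatize_sc(ref, adia, ...)
  res$sites <- sites
  res$n_ct_per_direction <- as.integer(n_ct_per_direction)
  class(res) <- c("pair_block", class(res))
  res
}

#' Look up one diabatized matrix element
#'
#' @param block A `pair_block` (or any `diabatization_result`).
#' @param label_i,label_j Basis-state labels; equal labels give an energy,
#'   distinct labels a coupling.
#' @return Matrix element in eV.
#' @export
pair_coupling <- function(block, label_i, label_j = label_i) {
  H <- block$H_d
  if (!label_i %in% rownames(H) || !label_j %in% rownames(H))
    stop("label not present in block: ",
         paste(setdiff(c(label_i, label_j), rownames(H)), collapse = ", "))
  H[label_i, label_j]
}

#' Intra-molecular parameters (site LE energies and La-Lb mixing)
#'
#' Builds the per-site diagonal part of the excitonic Hamiltonian: the LE
#' energies and the same-site La-Lb coupling, as perturbed by the molecular
#' environment.  Three parametrization routes are supported: `pair_averaged`
#' takes the unweighted mean of the same-site entries over every pair block
#' containing the site; `strand`/`tetrad` diabatize an LE-only reference set
#' on a larger supramolecular complex (strands are typically projected onto
#' 30 adiabatic states); `monomer` copies isolated-monomer values from the
#' sites' attached transition data.
#'
#' @param mode `"pair_averaged"`, `"strand"`, `"tetrad"` or `"monomer"`.
#' @param pairs List of `pair_block` (for `pair_averaged`).
#' @param sc_results List of `diabatization_result` from LE-only strand or
#'   tetrad projections (for `strand`/`tetrad`).
#' @param sites List of `chromophore_site` with `monomer_data` (for
#'   `"monomer"`); also used to check coverage in the other modes.
#' @param update_couplings For `strand`/`tetrad`: if `TRUE` (default) the
#'   same-site La-Lb couplings are also taken from the SC; if `FALSE` only
#'   the energies are updated and the couplings come from `pairs` (if given)
#'   or are zero.
#' @return Object of class `intra_params`: list with `site_ids`, `e_la`,
#'   `e_lb`, `v_lalb` (named numeric vectors, eV) and `provenance`.
#' @export
build_intra_params <- function(mode = c("pair_averaged", "strand", "tetrad",
                                        "monomer"),
                               pairs = NULL, sc_results = NULL, sites = NULL,
                               update_couplings = TRUE) {
  mode <- match.arg(mode)
  acc <- new.env()
  put <- function(site, what, val) {
    k <- as.character(site)
    cur <- acc[[k]]
    if (is.null(cur)) cur <- list(e_la = c(), e_lb = c(), v = c())
    cur[[what]] <- c(cur[[what]], val)
    acc[[k]] <- cur
  }
  harvest <- function(res_list) {
    for (b in res_list) {
      lab <- parse_labels(b$labels)
      for (s in unique(stats::na.omit(lab$site))) {
        la <- le_label(s, "La"); lb <- le_label(s, "Lb")
        if (la %in% b$labels) put(s, "e_la", b$H_d[la, la])
        if (lb %in% b$labels) put(s, "e_lb", b$H_d[lb, lb])
        if (all(c(la, lb) %in% b$labels)) put(s, "v", b$H_d[la, lb])
      }
    }
  }
  if (mode == "pair_averaged") {
    if (is.null(pairs) || !length(pairs))
      stop("pair_averaged mode requires pair blocks")
    harvest(pairs)
  } else if (mode %in% c("strand", "tetrad")) {
    if (is.null(sc_results) || !length(sc_results))
      stop(mode, " mode requires LE-only SC diabatization results")
    for (b in sc_results)
      if (any(parse_labels(b$labels)$kind == "CT"))
        stop("strand/tetrad intra parametrization must be LE-only")
    harvest(sc_results)
    if (!update_couplings) {
      for (k in ls(acc)) acc[[k]]$v <- c()
      if (!is.null(pairs)) {
        keep <- new.env()
        for (b in pairs) {
          lab <- parse_labels(b$labels)
          for (s in unique(stats::na.omit(lab$site))) {
            la <- le_label(s, "La"); lb <- le_label(s, "Lb")
            if (all(c(la, lb) %in% b$labels)) {
              cur <- acc[[as.character(s)]]
              if (!is.null(cur)) {
                cur$v <- c(cur$v, b$H_d[la, lb]); acc[[as.character(s)]] <- cur
              }
            }
          }
        }
      }
    }
  } else { # monomer
    if (is.null(sites)) stop("monomer mode requires sites with monomer_data")
    for (s in sites) {
      if (is.null(s$monomer_data))
        stop("site ", s$residue_label, " has no monomer_data")
      put(s$site_id, "e_la", s$monomer_data$states$La$energy)
      put(s$site_id, "e_lb", s$monomer_data$states$Lb$energy)
      put(s$site_id, "v", 0)   # LEs do not mix in the isolated monomer
    }
  }
  ids <- sort(as.integer(ls(acc)))
  if (!is.null(sites)) {
    want <- vapply(sites, function(s) s$site_id, integer(1))
    miss <- setdiff(want, ids)
    if (length(miss))
      stop("no intra parameters for site(s): ", paste(miss, collapse = ", "))
    ids <- sort(want)
  }
  g <- function(what) vapply(as.character(ids), function(k) {
    v <- acc[[k]][[what]]
    if (!length(v)) 0 else mean(v)
  }, numeric(1))
  structure(list(site_ids = ids, e_la = g("e_la"), e_lb = g("e_lb"),
                 v_lalb = g("v"), provenance = mode),
            class = "intra_params")
}

#' @export
print.intra_params <- function(x, ...) {
  cat(sprintf("<intra_params (%s) for %d sites; mean e_La %.3f eV, e_Lb %.3f eV>\n",
              x$provenance, length(x$site_ids), mean(x$e_la), mean(x$e_lb)))
  invisible(x)
}

# ---- parametrization interchange format -------------------------------------

#' Read or write the parametrization interchange file
#'
#' JSON interchange format for everything the Hamiltonian builder needs from
#' the upstream quantum-chemistry step: per-monomer transition data and, per
#' supramolecular complex, the reference labels, the overlap matrix S
#' (row-major), the adiabatic energies and the adiabatic transition dipoles
#' with a gauge flag.  The schema ships at
#' `system.file("schema", "parametrization-schema.json", package = "frdex")`.
#'
#' @param param For writing: list with `monomers` (named list of
#'   `monomer_transition_data`) and `scs` (list of lists with `ref`
#'   (`reference_overlap`), `adia` (`adiabatic_set`) and `kind`).
#' @param path File path.
#' @return The parametrization list (reading), or `path` (writing,
#'   invisibly).
#' @export
write_parametrization_json <- function(param, path) {
  enc_mon <- function(m) list(
    base_type = m$base_type,
    atom_names = m$atom_names,
    states = lapply(m$states, function(st) list(
      energy = st$energy, elec_tdip = st$elec_tdip, mag_tdip = st$mag_tdip,
      charges = as.numeric(st$charges))),
    gauge = m$gauge)
  enc_sc <- function(sc) list(
    sc_id = sc$adia$sc_id, kind = sc$kind, labels = sc$ref$labels,
    n_ref = nrow(sc$ref$S), n_adiabatic = ncol(sc$ref$S),
    S = as.numeric(t(sc$ref$S)),          # row-major
    energies = sc$adia$energies,
    elec_tdip = as.numeric(t(sc$adia$elec_tdip)),
    mag_tdip = as.numeric(t(sc$adia$mag_tdip)),
    gauge = sc$adia$gauge)
  jsonlite::write_json(list(format = "frdex-parametrization-v1",
                            monomers = lapply(param$monomers, enc_mon),
                            scs = lapply(param$scs, enc_sc)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parametrization_json
#' @export
read_parametrization_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                           simplifyDataFrame = FALSE)
  if (!identical(j$format, "frdex-parametrization-v1"))
    stop("not a frdex parametrization file: ", path)
  monomers <- lapply(j$monomers, function(m) {
    states <- lapply(m$states, function(st) list(
      energy = st$energy,
      elec_tdip = as.numeric(st$elec_tdip),
      mag_tdip = as.numeric(st$mag_tdip),
      charges = setNames(as.numeric(st$charges), m$atom_names)))
    monomer_transition_data(m$base_type, m$atom_names, states,
                            gauge = m$gauge)
  })
  scs <- lapply(j$scs, function(sc) {
    S <- matrix(as.numeric(sc$S), nrow = sc$n_ref, ncol = sc$n_adiabatic,
                byrow = TRUE)
    list(kind = sc$kind,
         ref = reference_overlap(unlist(sc$labels), S),
         adia = adiabatic_set(sc$sc_id, as.numeric(sc$energies),
                              matrix(as.numeric(sc$elec_tdip), ncol = 3,
                                     byrow = TRUE),
                              matrix(as.numeric(sc$mag_tdip), ncol = 3,
                                     byrow = TRUE),
                              gauge = sc$gauge))
  })
  list(monomers = monomers, scs = scs)
}
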