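# Decomposition of excitonic states into site/LE and pair/CT contributions:
# the machine-readable analyses linking spectral intensity to stacking
# geometry.

#' Composition of one excitonic state
#'
#' Partitions the (signed) eigenvector coefficients of state `k` by basis
#' label: per-(site, La/Lb) LE coefficients and per-ordered-pair CT weights
#' (summed squared coefficients over the orbital index), plus the total CT
#' percentage of the state.
#'
#' @param states An `exciton_states`.
#' @param k State index (1 = lowest energy).
#' @return Object of class `state_composition`: list with `k`, `energy`,
#'   `R`, `f`, `le_coef` (data frame site, alpha, coef, weight), `ct_weight`
#'   (data frame donor, acceptor, weight), `ct_percent`.
#' @export
state_composition <- function(states, k) {
  n <- length(states$energies)
  if (k < 1 || k > n) stop("state index out of range: ", k)
  if (is.null(states$basis)) stop("states carry no basis labels")
  C <- states$coefficients[, k]
  b <- states$basis
  le <- b$kind == "LE"
  le_coef <- data.frame(site = b$site[le], alpha = b$alpha[le],
                        coef = C[le], weight = C[le]^2)
  ctw <- NULL
  if (any(!le)) {
    key <- paste0(b$donor[!le], ">", b$acceptor[!le])
    w <- tapply(C[!le]^2, key, sum)
    da <- do.call(rbind, strsplit(names(w), ">", fixed = TRUE))
    ctw <- data.frame(donor = as.integer(da[, 1]),
                      acceptor = as.integer(da[, 2]),
                      weight = as.numeric(w))
    ctw <- ctw[order(ctw$donor, ctw$acceptor), , drop = FALSE]
    rownames(ctw) <- NULL
  } else {
    ctw <- data.frame(donor = integer(), acceptor = integer(),
                      weight = numeric())
  }
  structure(list(k = k, energy = states$energies[k],
                 R = if (!is.null(states$R)) states$R[k] else NA_real_,
                 f = if (!is.null(states$f)) states$f[k] else NA_real_,
                 le_coef = le_coef, ct_weight = ctw,
                 ct_percent = 100 * sum(ctw$weight)),
            class = "state_composition")
}

#' @export
print.state_composition <- function(x, ...) {
  dom <- x$le_coef[order(-x$le_coef$weight), ][1, ]
  cat(sprintf(
    "<state_composition k=%d: E=%.3f eV, R=%.3g, CT %.1f%%, dominant LE %s(%s)>\n",
    x$k, x$energy, x$R, x$ct_percent, paste0("site ", dom$site), dom$alpha))
  invisible(x)
}

#' Per-state band report
#'
#' Tabulates the lowest `n_loc * n_sites` excitonic states (the
#' predominantly-LE band: 24 states for a 12-guanine quadruplex core):
#' energy, rotational and oscillator strength, CT percentage and the
#' dominant LE site.
#'
#' @param states An `exciton_states`.
#' @param n_loc LEs per site (default 2).
#' @param n_sites Number of sites; default inferred from the basis.
#' @return Data frame with one row per state.
#' @export
band_report <- function(states, n_loc = 2L, n_sites = NULL) {
  if (is.null(states$basis)) stop("states carry no basis labels")
  if (is.null(n_sites))
    n_sites <- length(unique(stats::na.omit(states$basis$site)))
  n <- n_loc * n_sites
  if (length(states$energies) < n)
    stop("fewer states than n_loc * n_sites")
  rows <- lapply(seq_len(n), function(k) {
    comp <- state_composition(states, k)
    dom <- comp$le_coef[which.max(comp$le_coef$weight), ]
    data.frame(state = k, energy = comp$energy,
               wavelength = .ev2nm(comp$energy),
               R = comp$R, f = comp$f, ct_percent = comp$ct_percent,
               dominant_site = dom$site, dominant_alpha = dom$alpha,
               dominant_weight = dom$weight)
  })
  do.call(rbind, rows)
}

#' Pair stacking overlap with excitonic-state composition
#'
#' For an ensemble of structures (e.g. MD snapshots) pairs the interface
#' stacking overlap totals with the LE/CT involvement of selected excitonic
#' states (typically state 1, the bottom of the La band, and state
#' `n_sites + 1`, the bottom of the Lb band), enabling the
#' overlap-vs-intensity mechanism analysis.  Output is keyed by structure
#' id, independent of input order.
#'
#' @param overlap_reports Named list of `overlap_report` (names = structure
#'   ids).
#' @param compositions Named list (same names) of lists of
#'   `state_composition` for the selected states.
#' @return Data frame with one row per (structure, state): interface areas,
#'   the dominant stacked pair's CT weight and dominant LE weight, and the
#'   state's CT percentage.
#' @export
correlate_overlap_vs_composition <- function(overlap_reports, compositions) {
  ids <- sort(names(overlap_reports))
  if (!setequal(ids, names(compositions)))
    stop("mismatched structure ids between overlap reports and compositions")
  rows <- list()
  for (id in ids) {
    ov <- overlap_reports[[id]]
    for (comp in compositions[[id]]) {
      ctw <- comp$ct_weight
      if (nrow(ctw)) {
        pk <- .pair_key(ctw$donor, ctw$acceptor)
        agg <- tapply(ctw$weight, pk, sum)
        top <- names(agg)[which.max(agg)]
        top_w <- max(agg)
      } else { top <- NA_character_; top_w <- 0 }
      lw <- tapply(comp$le_coef$weight, comp$le_coef$site, sum)
      iface <- ov$interface_totals
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = id, state = comp$k, energy = comp$energy,
        R = comp$R, ct_percent = comp$ct_percent,
        dominant_ct_pair = top, dominant_ct_weight = top_w,
        dominant_le_site = as.integer(names(lw)[which.max(lw)]),
        dominant_le_weight = max(lw),
        interface = paste(iface$tetrad_a, iface$tetrad_b, sep = "/",
                          collapse = ";"),
        interface_area = paste(sprintf("%.6f", iface$area), collapse = ";"),
        total_overlap_area = sum(iface$area))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a state composition (or list of them) to JSON
#'
#' @param comp A `state_composition` or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_composition_json <- function(comp, path) {
  if (inherits(comp, "state_composition")) comp <- list(comp)
  jsonlite::write_json(lapply(comp, unclass), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
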