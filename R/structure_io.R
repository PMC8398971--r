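# Structure ingestion: reduce (multi-model) PDB files of nucleic acids to
# base chromophores, idealize base geometries against optimized templates,
# and compute the stacking descriptors used by the Hamiltonian builder.

# Base heavy-atom whitelists (ring + exocyclic heavy atoms).  Backbone
# stripping is by atom NAME against these tables, not by element, so sugar
# (C1', ...) and phosphate atoms as well as ions are excluded.
.base_atoms <- list(
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999)

.resname_to_base <- function(resid) {
  r <- toupper(resid)
  r <- sub("^D", "", r)           # DG/DA/DT -> G/A/T
  r <- sub("[35]$", "", r)        # terminal variants DG3/DG5
  switch(r, "G" = "G", "GUA" = "G",
            "A" = "A", "ADE" = "A",
            "T" = "T", "THY" = "T",
            NA_character_)
}

#' Atom-name whitelist for a base type
#'
#' Heavy atoms (ring plus exocyclic substituents) retained for a base after
#' backbone stripping.  Guanine: N9 C8 N7 C5 C6 O6 N1 C2 N2 N3 C4; adenine:
#' N9 C8 N7 C5 C6 N6 N1 C2 N3 C4; thymine: N1 C2 O2 N3 C4 O4 C5 C7 C6.
#'
#' @param base_type One of "G", "A", "T".
#' @return Character vector of atom names.
#' @export
base_atom_whitelist <- function(base_type) {
  w <- .base_atoms[[base_type]]
  if (is.null(w)) stop("unknown base type: ", base_type)
  w
}

#' Construct a chromophore site
#'
#' A chromophore site is one nucleobase reduced to its heavy base atoms, the
#' unit on which local excitations are defined.  The centre of mass is
#' recomputed from the atoms (standard atomic masses).
#'
#' @param site_id Integer index.
#' @param residue_label String, e.g. `"G10"` or `"A:DG:10"`.
#' @param base_type `"G"`, `"A"` or `"T"`.
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param ring_atoms Character subset of `atoms$name` defining the ring +
#'   exocyclic polygon; defaults to all atoms.
#' @param monomer_data Optional `monomer_transition_data` attached to the
#'   site (already rotated into the site frame).
#' @return Object of class `chromophore_site`.
#' @export
chromophore_site <- function(site_id, residue_label, base_type, atoms,
                             ring_atoms = atoms$name, monomer_data = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (!all(ring_atoms %in% atoms$name))
    stop("ring_atoms must be a subset of atom names")
  if (anyDuplicated(atoms$name))
    stop("duplicate atom names in residue ", residue_label)
  m <- .atomic_mass[atoms$element]
  if (anyNA(m)) stop("unknown element in residue ", residue_label)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  structure(list(site_id = as.integer(site_id),
                 residue_label = residue_label,
                 base_type = base_type,
                 atoms = atoms,
                 ring_atoms = ring_atoms,
                 com = as.numeric(com),
                 monomer_data = monomer_data),
            class = "chromophore_site")
}

#' @export
print.chromophore_site <- function(x, ...) {
  cat(sprintf("<chromophore_site %d %s (%s), %d atoms, com = [%.2f %.2f %.2f]>\n",
              x$site_id, x$residue_label, x$base_type, nrow(x$atoms),
              x$com[1], x$com[2], x$com[3]))
  invisible(x)
}

#' Coordinates of (a subset of) a site's atoms
#'
#' @param site A `chromophore_site`.
#' @param names Atom names to extract, in that order; default all.
#' @return n x 3 matrix (Angstrom), rownames = atom names.
#' @export
site_coords <- function(site, names = site$atoms$name) {
  idx <- match(names, site$atoms$name)
  if (anyNA(idx)) stop("atoms not present: ",
                       paste(names[is.na(idx)], collapse = ", "))
  m <- as.matrix(site$atoms[idx, c("x", "y", "z")])
  rownames(m) <- names
  m
}

#' Read base chromophores from a PDB file
#'
#' Parses a (possibly multi-model) PDB file and returns one
#' `chromophore_site` per nucleobase residue, in residue order.  The sugar
#' backbone, phosphates, hydrogens, ions and water are removed: only heavy
#' atoms on the per-base whitelist ([base_atom_whitelist()]) are kept.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model number (NMR/MD snapshot).
#' @param strict If `TRUE` (default), a base residue missing whitelist atoms
#'   is an error naming the residue; if `FALSE` it is skipped.
#' @return List of `chromophore_site`.
#' @export
read_structure <- function(path, model_index = 1L, strict = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models)
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, n_models))
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  key <- paste(at$chain, at$resno, at$resid, sep = "|")
  sites <- list()
  sid <- 0L
  for (k in unique(key)) {
    rows <- at[key == k, , drop = FALSE]
    base <- .resname_to_base(rows$resid[1])
    if (is.na(base)) next                       # ion, water, ligand
    want <- .base_atoms[[base]]
    rows <- rows[rows$elety %in% want, , drop = FALSE]
    lbl <- paste0(base, rows$resno[1])
    if (nrow(rows) < length(want)) {
      if (strict)
        stop("residue ", lbl, " (chain ", rows$chain[1],
             ") is missing base atoms: ",
             paste(setdiff(want, rows$elety), collapse = ", "))
      next
    }
    rows <- rows[match(want, rows$elety), , drop = FALSE]
    sid <- sid + 1L
    sites[[sid]] <- chromophore_site(
      site_id = sid, residue_label = lbl, base_type = base,
      atoms = data.frame(name = rows$elety,
                         element = substr(rows$elety, 1, 1),
                         x = rows$x, y = rows$y, z = rows$z))
  }
  if (!length(sites)) stop("no nucleobase residues found in ", path)
  sites
}

#' Write chromophore sites as a (multi-model) PDB file
#'
#' Counterpart of [read_structure()]; used by the synthetic generator to emit
#' geometries the rest of the pipeline ingests.  Each element of `models` is
#' a list of `chromophore_site`.
#'
#' @param models A list of site lists (one per model), or a single site list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(models, path) {
  if (!is.null(models[[1]]$atoms)) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (mi in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (s in models[[mi]]) {
      res <- paste0("D", s$base_type)
      for (i in seq_len(nrow(s$atoms))) {
        serial <- serial + 1L
        a <- s$atoms[i, ]
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, a$name, res, s$site_id, a$x, a$y, a$z, a$element), con)
      }
    }
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Replace a base geometry by a rigidly superposed template
#'
#' Each base extracted from an experimental or MD structure is replaced by an
#' optimized template of the same base type, rigidly superposed onto the
#' original by [kabsch_superpose()] over the name-matched heavy atoms.  The
#' result has the template's internal geometry exactly (all bond lengths and
#' angles), posed like the original base.
#'
#' @param site A `chromophore_site`.
#' @param template A `chromophore_site` of the same `base_type` whose
#'   geometry is to be imposed (e.g. [guanine_template()]).
#' @return A new `chromophore_site` with template geometry; `residue_label`,
#'   `site_id` and any attached `monomer_data` are preserved.
#' @export
idealize_base <- function(site, template) {
  if (site$base_type != template$base_type)
    stop("base-type mismatch: site is ", site$base_type,
         ", template is ", template$base_type)
  common <- intersect(template$atoms$name, site$atoms$name)
  mandatory <- base_atom_whitelist(site$base_type)
  if (!all(mandatory %in% common))
    stop("unmatched mandatory atoms for ", site$residue_label, ": ",
         paste(setdiff(mandatory, common), collapse = ", "))
  fit <- kabsch_superpose(site_coords(template, common),
                          site_coords(site, common))
  new_xyz <- sweep(site_coords(template) %*% fit$rotation, 2,
                   fit$translation, "+")
  atoms <- template$atoms
  atoms$x <- new_xyz[, 1]; atoms$y <- new_xyz[, 2]; atoms$z <- new_xyz[, 3]
  chromophore_site(site$site_id, site$residue_label, site$base_type, atoms,
                   ring_atoms = template$ring_atoms,
                   monomer_data = site$monomer_data)
}

#' Centre-of-mass distance between two bases
#'
#' @param site_i,site_j `chromophore_site` objects.
#' @return Euclidean distance between base heavy-atom centres of mass
#'   (Angstrom).
#' @export
com_distance <- function(site_i, site_j) {
  .norm3(site_i$com - site_j$com)
}

#' Stacking overlap area of two bases
#'
#' Projects the ring + exocyclic atoms of both bases onto the common mean
#' plane of the pair -- the plane through the midpoint of the two ring
#' centroids whose normal is the (sign-aligned) average of the two base
#' normals, so the measure is symmetric in i and j -- and returns the
#' intersection area of the two projected convex outlines.  This is the
#' per-pair overlap summed in [interface_overlap_totals()].
#'
#' @param site_i,site_j `chromophore_site` objects (distinct).
#' @return Overlap area in Angstrom^2 (>= 0).
#' @export
stacking_overlap_area <- function(site_i, site_j) {
  if (site_i$site_id == site_j$site_id &&
      identical(site_i$residue_label, site_j$residue_label))
    stop("overlap area of a site with itself is undefined")
  xi <- site_coords(site_i, site_i$ring_atoms)
  xj <- site_coords(site_j, site_j$ring_atoms)
  pli <- base_plane(xi); plj <- base_plane(xj)
  nj <- plj$normal * sign(sum(pli$normal * plj$normal))
  normal <- .unit3(pli$normal + nj)
  point <- (pli$point + plj$point) / 2
  B <- .plane_basis(normal)
  pi2 <- sweep(xi, 2, point) %*% B
  pj2 <- sweep(xj, 2, point) %*% B
  .hull_intersection_area(pi2, pj2)
}

# ---- neighbour classification -----------------------------------------------

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

.new_neighbor_graph <- function(pairs, provenance) {
  if (is.null(pairs) || !nrow(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(), class = character())
  }
  ii <- pmin(pairs$i, pairs$j); jj <- pmax(pairs$i, pairs$j)
  pairs <- data.frame(i = ii, j = jj, class = pairs$class)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  if (any(pairs$i == pairs$j)) stop("self-pairs are not allowed")
  if (anyDuplicated(.pair_key(pairs$i, pairs$j)))
    stop("each pair must have exactly one class")
  structure(list(pairs = pairs, provenance = provenance),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph (%s): %d pairs (%s)>\n", x$provenance,
              nrow(x$pairs),
              paste(sprintf("%s=%d", names(table(x$pairs$class)),
                            table(x$pairs$class)), collapse = ", ")))
  invisible(x)
}

#' Classify nearest-neighbour base pairs
#'
#' Nearest neighbours of a G-quadruplex core come in three classes:
#' `stacked` (bases immediately stacked on top of one another in adjacent
#' tetrads, i.e. consecutive along a strand), `hbonded` (Hoogsteen partners
#' within the same tetrad) and `diagonal` (a base in one tetrad with an
#' H-bond neighbour of its stacking partner in the adjacent tetrad, e.g.
#' G1-G5 or G1-G8 in the 3-tetrad antiparallel fold).  With an explicit
#' `topology` (preferred, and independent of coordinates) the classes follow
#' these definitions literally; otherwise they are inferred from geometry
#' with configurable cutoffs.
#'
#' @param sites List of `chromophore_site`.
#' @param topology Optional list with `tetrads` (list of length-4 site-id
#'   vectors in cyclic Hoogsteen order, bottom tetrad first) and `strands`
#'   (list of site-id vectors in strand order).
#' @param cutoffs Geometric thresholds used when `topology` is `NULL`:
#'   `stack_dist` (COM distance, default 5.0), `plane_angle` (degrees, 30),
#'   `hb_dist` (COM distance for H-bonded, 9.0), `contact_dist` (N/O
#'   donor-acceptor contact, 3.5), `stack_rise_min` (minimum out-of-plane COM
#'   offset for stacking, 2.0), `hb_rise_max` (maximum offset for coplanar
#'   partners, 1.5).
#' @return A `neighbor_graph`.
#' @export
classify_neighbors <- function(sites, topology = NULL,
                               cutoffs = list()) {
  ids <- vapply(sites, function(s) s$site_id, integer(1))
  if (!is.null(topology)) {
    tet <- topology$tetrads
    if (is.null(tet)) stop("topology must contain 'tetrads'")
    tids <- unlist(tet)
    if (!all(tids %in% ids))
      stop("topology references site ids absent from the structure")
    if (any(lengths(tet) != 4L)) stop("each tetrad must contain 4 sites")
    hb <- NULL
    for (t in tet) {
      for (k in 1:4)
        hb <- rbind(hb, c(t[k], t[if (k == 4) 1 else k + 1]))
    }
    st <- NULL
    if (!is.null(topology$strands)) {
      for (s in topology$strands) {
        s <- s[s %in% tids]        # loop residues never stack "in register"
        if (length(s) > 1L)
          for (k in seq_len(length(s) - 1L)) st <- rbind(st, c(s[k], s[k + 1]))
      }
    }
    key_hb <- .pair_key(hb[, 1], hb[, 2])
    key_st <- if (is.null(st)) character() else .pair_key(st[, 1], st[, 2])
    # diagonal: i with H-bond partners of i's stacking partner
    dg <- NULL
    if (!is.null(st)) {
      hb_partners <- function(x) c(hb[hb[, 1] == x, 2], hb[hb[, 2] == x, 1])
      for (r in seq_len(nrow(st))) {
        a <- st[r, 1]; b <- st[r, 2]
        for (p in hb_partners(b)) dg <- rbind(dg, c(a, p))
        for (p in hb_partners(a)) dg <- rbind(dg, c(b, p))
      }
      key_dg <- setdiff(unique(.pair_key(dg[, 1], dg[, 2])),
                        c(key_hb, key_st))
    } else key_dg <- character()
    split2 <- function(keys) if (!length(keys)) NULL else {
      m <- do.call(rbind, strsplit(keys, "-"))
      data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
    }
    pairs <- rbind(
      if (length(key_st)) cbind(split2(unique(key_st)), class = "stacked"),
      if (length(key_hb)) cbind(split2(unique(key_hb)), class = "hbonded"),
      if (length(key_dg)) cbind(split2(key_dg), class = "diagonal"))
    return(.new_neighbor_graph(pairs, "topology_file"))
  }

  # geometric inference
  ct <- modifyList(list(stack_dist = 5.0, plane_angle = 30, hb_dist = 9.0,
                        contact_dist = 3.5, stack_rise_min = 2.0,
                        hb_rise_max = 1.5), cutoffs)
  n <- length(sites)
  normals <- lapply(sites, function(s) base_plane(s)$normal)
  pairs <- NULL
  ambiguous <- character()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    si <- sites[[a]]; sj <- sites[[b]]
    d <- com_distance(si, sj)
    if (d > ct$hb_dist) next
    ang <- acos(pmin(1, abs(sum(normals[[a]] * normals[[b]])))) * 180 / pi
    if (ang > ct$plane_angle) next
    nav <- .unit3(normals[[a]] + normals[[b]] *
                    sign(sum(normals[[a]] * normals[[b]])))
    rise <- abs(sum((sj$com - si$com) * nav))
    is_stack <- d < ct$stack_dist && rise > ct$stack_rise_min
    contacts <- 0L
    if (rise < ct$hb_rise_max) {
      xi <- site_coords(si); xj <- site_coords(sj)
      no_i <- xi[si$atoms$element %in% c("N", "O"), , drop = FALSE]
      no_j <- xj[sj$atoms$element %in% c("N", "O"), , drop = FALSE]
      dd <- sqrt(outer(rowSums(no_i^2), rowSums(no_j^2), "+") -
                 2 * no_i %*% t(no_j))
      contacts <- sum(dd < ct$contact_dist)
    }
    is_hb <- contacts >= 2L
    if (is_stack && is_hb) {
      ambiguous <- c(ambiguous, .pair_key(si$site_id, sj$site_id)); next
    }
    if (is_stack)
      pairs <- rbind(pairs, data.frame(i = si$site_id, j = sj$site_id,
                                       class = "stacked"))
    else if (is_hb)
      pairs <- rbind(pairs, data.frame(i = si$site_id, j = sj$site_id,
                                       class = "hbonded"))
  }
  if (length(ambiguous))
    stop("ambiguous geometric assignment (stacked AND hbonded) for pairs: ",
         paste(ambiguous, collapse = ", "))
  # compose diagonals from the inferred stacked/hbonded sets
  if (!is.null(pairs)) {
    st <- pairs[pairs$class == "stacked", , drop = FALSE]
    hb <- pairs[pairs$class == "hbonded", , drop = FALSE]
    have <- .pair_key(pairs$i, pairs$j)
    hb_partners <- function(x) c(hb$j[hb$i == x], hb$i[hb$j == x])
    dg <- NULL
    for (r in seq_len(nrow(st))) {
      for (p in hb_partners(st$j[r])) dg <- rbind(dg, c(st$i[r], p))
      for (p in hb_partners(st$i[r])) dg <- rbind(dg, c(st$j[r], p))
    }
    if (!is.null(dg)) {
      kd <- setdiff(unique(.pair_key(dg[, 1], dg[, 2])), have)
      if (length(kd)) {
        m <- do.call(rbind, strsplit(kd, "-"))
        pairs <- rbind(pairs, data.frame(i = as.integer(m[, 1]),
                                         j = as.integer(m[, 2]),
                                         class = "diagonal"))
      }
    }
  }
  .new_neighbor_graph(pairs, "geometric")
}

#' Per-interface stacking overlap report
#'
#' Sums the [stacking_overlap_area()] of every stacked pair over each tetrad
#' interface (e.g. the diagonal-loop-side/middle and middle/lateral-loop-side
#' interfaces of a 3-tetrad fold), the quantity whose thermal fluctuation
#' modulates the low-energy CD intensity.
#'
#' @param sites List of `chromophore_site`.
#' @param graph A `neighbor_graph`.
#' @param tetrad_assignment List of site-id vectors, one per tetrad, in
#'   stacking order (interface k is between tetrad k and k+1).
#' @return Object of class `overlap_report`: list with `per_pair_area`
#'   (data frame i, j, area), `per_pair_com_distance`, and
#'   `interface_totals` (data frame tetrad_a, tetrad_b, area).
#' @export
interface_overlap_totals <- function(sites, graph, tetrad_assignment) {
  ids <- vapply(sites, function(s) s$site_id, integer(1))
  byid <- setNames(sites, as.character(ids))
  gids <- ids[vapply(sites, function(s) s$base_type == "G", logical(1))]
  if (!all(gids %in% unlist(tetrad_assignment)))
    stop("tetrad assignment must cover all G sites")
  tet_of <- integer()
  for (t in seq_along(tetrad_assignment))
    tet_of[as.character(tetrad_assignment[[t]])] <- t
  st <- graph$pairs[graph$pairs$class == "stacked", , drop = FALSE]
  per <- data.frame(i = st$i, j = st$j, area = NA_real_, com_dist = NA_real_,
                    ta = NA_integer_, tb = NA_integer_)
  for (r in seq_len(nrow(st))) {
    si <- byid[[as.character(st$i[r])]]; sj <- byid[[as.character(st$j[r])]]
    ta <- tet_of[as.character(st$i[r])]; tb <- tet_of[as.character(st$j[r])]
    if (is.na(ta) || is.na(tb) || abs(ta - tb) != 1L)
      stop(sprintf("stacked pair %d-%d does not span adjacent tetrads",
                   st$i[r], st$j[r]))
    per$area[r] <- stacking_overlap_area(si, sj)
    per$com_dist[r] <- com_distance(si, sj)
    per$ta[r] <- min(ta, tb); per$tb[r] <- max(ta, tb)
  }
  key <- paste(per$ta, per$tb, sep = "/")
  tot <- tapply(per$area, key, sum)
  iface <- do.call(rbind, strsplit(names(tot), "/"))
  totals <- data.frame(tetrad_a = as.integer(iface[, 1]),
                       tetrad_b = as.integer(iface[, 2]),
                       area = as.numeric(tot))
  totals <- totals[order(totals$tetrad_a), , drop = FALSE]
  rownames(totals) <- NULL
  structure(list(per_pair_area = per[, c("i", "j", "area")],
                 per_pair_com_distance = per[, c("i", "j", "com_dist")],
                 interface_totals = totals),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n interface totals (A^2):\n")
  print(x$interface_totals, row.names = FALSE)
  invisible(x)
}

# ---- topology / report JSON io ----------------------------------------------

#' Write or read a tetrad/strand topology file
#'
#' The topology file is a JSON object with `tetrads` (list of 4-vectors of
#' site ids in cyclic Hoogsteen order, bottom first), `strands` (site-id
#' vectors in strand order) and optional `loops`.
#'
#' @param topology Topology list.
#' @param path File path.
#' @return `write_topology_json`: `path` invisibly; `read_topology_json`:
#'   the topology list.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(topology, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  top <- jsonlite::read_json(path, simplifyVector = TRUE)
  top$tetrads <- lapply(seq_len(nrow(top$tetrads)),
                        function(i) as.integer(top$tetrads[i, ]))
  if (!is.null(top$strands) && is.matrix(top$strands))
    top$strands <- lapply(seq_len(nrow(top$strands)),
                          function(i) as.integer(top$strands[i, ]))
  top
}

#' Serialize a neighbour graph or overlap report to JSON
#'
#' @param x A `neighbor_graph` or `overlap_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
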