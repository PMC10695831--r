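# Lipid-protein contact statistics from coarse bead trajectories:
# distance-cutoff contact counting with minimum-image periodicity,
# concentration/time normalization, and dual-cutoff site occupancy.

#' Contact analysis configuration
#'
#' Distance cutoffs in nm: 0.55 defines a contact; 0.475 and 0.8 are the
#' short/long cutoffs of the dual-cutoff (hysteresis) occupancy scheme
#' used for residence-time style binding analysis.
#'
#' @param contact_cutoff contact definition cutoff (nm).
#' @param occupancy_cutoff_short entry cutoff for a bound interval (nm).
#' @param occupancy_cutoff_long exit cutoff ending a bound interval (nm).
#' @export
contact_config <- function(contact_cutoff = 0.55,
                           occupancy_cutoff_short = 0.475,
                           occupancy_cutoff_long = 0.8) {
  stopifnot(contact_cutoff > 0,
            occupancy_cutoff_short > 0,
            occupancy_cutoff_short < occupancy_cutoff_long)
  structure(list(contact_cutoff = contact_cutoff,
                 occupancy_cutoff_short = occupancy_cutoff_short,
                 occupancy_cutoff_long = occupancy_cutoff_long),
            class = "contact_config")
}

#' Build a trajectory object
#'
#' A trajectory holds per-frame bead coordinates (nm) for protein
#' particles grouped by residue and lipid particles grouped by molecule
#' with a species label, plus an optional orthorhombic periodic box.
#'
#' @param frames list of frames; each frame is a list with `protein`
#'   (data.frame: `residue`, `x`, `y`, `z`) and `lipids` (data.frame:
#'   `mol`, `species`, `x`, `y`, `z`).
#' @param box periodic box lengths `c(x, y, z)` in nm, or `NULL` for a
#'   non-periodic system. Triclinic boxes are not supported.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, box = NULL) {
  if (!length(frames)) stop("empty trajectory")
  if (!is.null(box)) {
    if (is.matrix(box) || length(box) != 3)
      stop("only orthorhombic boxes c(x, y, z) are supported; ",
           "triclinic boxes are rejected")
    if (any(box <= 0)) stop("box lengths must be positive")
  }
  np <- vapply(frames, function(f) nrow(f$protein), integer(1))
  nl <- vapply(frames, function(f) nrow(f$lipids), integer(1))
  if (length(unique(np)) != 1 || length(unique(nl)) != 1)
    stop("particle counts must be consistent across frames")
  structure(list(frames = frames, box = box,
                 n_frames = length(frames)), class = "trajectory")
}

#' Parse a long-format frame table into a trajectory
#'
#' Adapter for plain-text trajectory exports: one row per bead per frame
#' with columns `frame`, `role` ("protein"/"lipid"), `group` (residue id
#' for protein beads, molecule id for lipid beads), `species` (lipid
#' species; ignored for protein), `x`, `y`, `z` (nm).
#'
#' @param table data.frame in the long format above.
#' @param box optional orthorhombic box lengths (nm).
#' @return a [trajectory()].
#' @export
as_trajectory <- function(table, box = NULL) {
  need <- c("frame", "role", "group", "x", "y", "z")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("frame table missing: ", paste(miss, collapse = ", "))
  frames <- lapply(split(table, table$frame), function(fr) {
    p <- fr[fr$role == "protein", ]
    l <- fr[fr$role == "lipid", ]
    list(protein = data.frame(residue = p$group, x = p$x, y = p$y, z = p$z),
         lipids = data.frame(mol = l$group,
                             species = if ("species" %in% names(l)) l$species
                                       else "lipid",
                             x = l$x, y = l$y, z = l$z))
  })
  trajectory(frames[order(as.numeric(names(frames)))], box = box)
}

# minimum-image pairwise distances between bead sets A (n x 3), B (m x 3)
pair_dists <- function(A, B, box) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (j in 1:3) {
    d <- outer(A[, j], B[, j], "-")
    if (!is.null(box)) d <- d - box[j] * round(d / box[j])
    d2 <- d2 + d * d
  }
  sqrt(d2)
}

frame_xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

#' Count lipid-protein contacts
#'
#' A residue and a lipid molecule are in contact in a frame when any of
#' their bead pairs lies within the contact cutoff (0.55 nm by default);
#' each residue-molecule pair contributes at most 1 per frame, and counts
#' accumulate over frames, per residue and per lipid species. The
#' minimum-image convention applies when a periodic box is present.
#'
#' @param traj a [trajectory()].
#' @param cfg a [contact_config()].
#' @return integer matrix, residues x species, of raw contact counts.
#' @export
contact_counts <- function(traj, cfg = contact_config()) {
  stopifnot(inherits(traj, "trajectory"))
  f1 <- traj$frames[[1]]
  residues <- unique(f1$protein$residue)
  species <- unique(f1$lipids$species)
  counts <- matrix(0L, length(residues), length(species),
                   dimnames = list(as.character(residues), species))
  for (fr in traj$frames) {
    if (any(!is.finite(frame_xyz(fr$protein))) ||
        any(!is.finite(frame_xyz(fr$lipids))))
      stop("non-finite coordinates in trajectory")
    D <- pair_dists(frame_xyz(fr$protein), frame_xyz(fr$lipids), traj$box)
    in_contact <- D <= cfg$contact_cutoff
    for (ri in seq_along(residues)) {
      rsel <- fr$protein$residue == residues[ri]
      if (!any(rsel)) next
      hit_beads <- colSums(in_contact[rsel, , drop = FALSE]) > 0
      if (!any(hit_beads)) next
      mols_hit <- unique(fr$lipids[hit_beads, c("mol", "species")])
      tab <- table(factor(mols_hit$species, levels = species))
      counts[ri, ] <- counts[ri, ] + as.integer(tab)
    }
  }
  counts
}

#' Normalize contact counts by lipid count and frame number
#'
#' normalized(r, s) = raw(r, s) / (n_lipids(s) * n_frames), making counts
#' comparable across species concentrations and simulation lengths.
#'
#' @param raw residue x species count matrix from [contact_counts()].
#' @param n_lipids named vector of lipid molecule counts per species.
#' @param n_frames number of frames accumulated.
#' @return An object of class `contact_profile` with `raw` and
#'   `normalized` matrices; species with zero lipids are NA.
#' @export
normalize_contacts <- function(raw, n_lipids, n_frames) {
  stopifnot(n_frames >= 1)
  species <- colnames(raw)
  miss <- setdiff(species, names(n_lipids))
  if (length(miss)) stop("lipid counts missing for: ",
                         paste(miss, collapse = ", "))
  nl <- n_lipids[species]
  norm <- sweep(raw, 2, nl * n_frames, "/")
  if (any(nl == 0)) {
    warning("species with zero lipids reported as NA: ",
            paste(species[nl == 0], collapse = ", "))
    norm[, nl == 0] <- NA_real_
  }
  structure(list(raw = raw, normalized = norm, n_lipids = nl,
                 n_frames = n_frames), class = "contact_profile")
}

#' Dual-cutoff site occupancy
#'
#' Fraction of frames during which at least one lipid of the given
#' species is bound at a residue site, under the dual-cutoff hysteresis
#' scheme: a molecule's bound interval starts when its minimum distance
#' to any site bead drops to the short cutoff (0.475 nm) and ends only
#' when it exceeds the long cutoff (0.8 nm), suppressing rapid rebinding
#' artifacts in residence-time analysis.
#'
#' @param traj a [trajectory()].
#' @param site_residues residue identifiers forming the binding site.
#' @param species lipid species to score.
#' @param cfg a [contact_config()].
#' @return occupancy fraction in [0, 1].
#' @export
site_occupancy <- function(traj, site_residues, species,
                           cfg = contact_config()) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(site_residues)) stop("site must be non-empty")
  f1 <- traj$frames[[1]]
  unknown <- setdiff(as.character(site_residues),
                     as.character(unique(f1$protein$residue)))
  if (length(unknown))
    stop("unknown site residues: ", paste(unknown, collapse = ", "))
  mols <- unique(f1$lipids$mol[f1$lipids$species == species])
  if (!length(mols)) stop("no lipids of species '", species, "' present")

  bound <- setNames(rep(FALSE, length(mols)), mols)
  frames_occupied <- 0L
  for (fr in traj$frames) {
    site_sel <- fr$protein$residue %in% site_residues
    P <- frame_xyz(fr$protein)[site_sel, , drop = FALSE]
    lip <- fr$lipids[fr$lipids$species == species, , drop = FALSE]
    D <- pair_dists(P, frame_xyz(lip), traj$box)
    for (mi in seq_along(mols)) {
      msel <- lip$mol == mols[mi]
      dmin <- min(D[, msel, drop = FALSE])
      if (dmin <= cfg$occupancy_cutoff_short) bound[mi] <- TRUE
      else if (dmin > cfg$occupancy_cutoff_long) bound[mi] <- FALSE
      # between the cutoffs the previous state persists
    }
    if (any(bound)) frames_occupied <- frames_occupied + 1L
  }
  frames_occupied / traj$n_frames
}
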