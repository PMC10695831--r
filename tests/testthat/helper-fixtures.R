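# Fixtures built in code for the enrichment and contact tests.

# a structure whose every slab holds exactly `per_aa` residues of each
# amino acid; optionally `extra_k` additional lysines in `band_slabs`
uniform_structure <- function(slabs = 0:4, per_aa = 1, extra_k = 0,
                              band_slabs = integer(0), half_thickness = 15) {
  aa <- asymfold:::AA1
  rows <- do.call(rbind, lapply(slabs, function(s) {
    df <- data.frame(resname = rep(aa, per_aa), ca_z = s + 0.5)
    if (extra_k > 0 && s %in% band_slabs)
      df <- rbind(df, data.frame(resname = rep("K", extra_k), ca_z = s + 0.5))
    df
  }))
  rows$chain <- "A"
  rows$resnum <- seq_len(nrow(rows))
  rows$region <- "soluble"
  rows$side <- ifelse(rows$ca_z > 0, "extracellular", "periplasmic")
  membrane_structure(rows, half_thickness)
}

# one frame with a single-bead site residue at the origin and one lipid
# bead at distance d along x
frame_at_distance <- function(d, species = "DMPG") {
  list(protein = data.frame(residue = 1, x = 0, y = 0, z = 0),
       lipids = data.frame(mol = "L1", species = species,
                           x = d, y = 0, z = 0))
}

# brute-force minimum-image contact counts over explicit image shifts
brute_contacts <- function(traj, cutoff) {
  f1 <- traj$frames[[1]]
  residues <- unique(f1$protein$residue)
  species <- unique(f1$lipids$species)
  counts <- matrix(0L, length(residues), length(species),
                   dimnames = list(as.character(residues), species))
  shifts <- expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  for (fr in traj$frames) {
    for (ri in seq_along(residues)) {
      P <- fr$protein[fr$protein$residue == residues[ri], c("x", "y", "z")]
      for (mol in unique(fr$lipids$mol)) {
        L <- fr$lipids[fr$lipids$mol == mol, ]
        sp <- L$species[1]
        hit <- FALSE
        for (pi in seq_len(nrow(P))) for (li in seq_len(nrow(L))) {
          base <- c(L$x[li] - P$x[pi], L$y[li] - P$y[pi], L$z[li] - P$z[pi])
          for (si in seq_len(nrow(shifts))) {
            dd <- base + unlist(shifts[si, ]) *
              (if (is.null(traj$box)) c(0, 0, 0) else traj$box)
            if (sqrt(sum(dd^2)) <= cutoff) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) counts[ri, sp] <- counts[ri, sp] + 1L
      }
    }
  }
  counts
}
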