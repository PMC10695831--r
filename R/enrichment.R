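# Membrane-depth residue-enrichment analysis: 1 Angstrom slab profiles,
# log2 enrichment against whole-protein or soluble-only backgrounds with
# separate enrichment/depletion sigma thresholds, positive-patch (PEP)
# detection, and the sequence-mode residue-count -> distance calibration.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# normalize residue names (1- or 3-letter) to 1-letter; NA when unknown
aa_one <- function(resname) {
  r <- toupper(resname)
  out <- ifelse(r %in% AA1, r, AA1[match(r, AA3)])
  out
}

#' Membrane-aligned structure
#'
#' A residue table for one protein aligned in the membrane frame: the
#' membrane normal is z, the origin is the membrane centre and the
#' extracellular side is positive. Each residue carries its C-alpha z
#' coordinate, a region label (`TM` or `soluble`) and a side label
#' (`extracellular`, `periplasmic` or `membrane`). When region/side are
#' absent they are inferred from `|ca_z| <= half_thickness` and the sign
#' of `ca_z`.
#'
#' @param residues data.frame with columns `resname`, `chain`, `resnum`,
#'   `ca_z` and optionally `region`, `side`.
#' @param half_thickness half bilayer thickness (Angstrom); the
#'   outer-leaflet plane sits at `+half_thickness`.
#' @return An object of class `membrane_structure`.
#' @export
membrane_structure <- function(residues, half_thickness) {
  need <- c("resname", "chain", "resnum", "ca_z")
  miss <- setdiff(need, names(residues))
  if (length(miss)) stop("residue table missing: ", paste(miss, collapse = ", "))
  if (!(half_thickness > 0)) stop("'half_thickness' must be positive")
  if (any(abs(residues$ca_z) >= 150, na.rm = TRUE))
    stop("|ca_z| must be < 150 Angstrom: is the structure membrane-centred?")
  if (!"region" %in% names(residues))
    residues$region <- ifelse(abs(residues$ca_z) <= half_thickness,
                              "TM", "soluble")
  if (!"side" %in% names(residues))
    residues$side <- ifelse(residues$region == "TM", "membrane",
                            ifelse(residues$ca_z > 0, "extracellular",
                                   "periplasmic"))
  structure(list(residues = residues, half_thickness = half_thickness),
            class = "membrane_structure")
}

#' Read a membrane-aligned structure from a PDB file
#'
#' Reads C-alpha records from a PDB whose frame follows the membrane
#' convention (z along the normal, origin at the membrane centre, as in
#' OPM depositions) and optionally joins a companion annotation table
#' with per-residue region/side labels.
#'
#' @param pdb_file path to a PDB file.
#' @param half_thickness half bilayer thickness (Angstrom).
#' @param annotations optional data.frame with columns `chain`, `resnum`,
#'   `region`, `side` (and optionally `conf`).
#' @return a [membrane_structure()].
#' @export
read_membrane_structure <- function(pdb_file, half_thickness,
                                    annotations = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(pdb_file)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  res <- data.frame(resname = ca$resid, chain = ca$chain,
                    resnum = ca$resno, ca_z = ca$z,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    key <- paste(res$chain, res$resnum)
    akey <- paste(annotations$chain, annotations$resnum)
    m <- match(key, akey)
    res$region <- annotations$region[m]
    res$side <- annotations$side[m]
    if ("conf" %in% names(annotations)) res$conf <- annotations$conf[m]
  }
  membrane_structure(res, half_thickness)
}

#' Pool structures into a 1-Angstrom slab profile
#'
#' Splits space into slabs parallel to the membrane plane and assigns
#' every residue to the half-open slab `[i, i+1)` containing its C-alpha
#' z coordinate (`i = floor(z / slab_width)`). Counts are pooled across
#' structures; residues with missing C-alpha positions or non-standard
#' names are skipped and counted. Per-amino-acid totals are kept for
#' both background modes (whole protein and soluble-only).
#'
#' @param structures a `membrane_structure` or list of them.
#' @param slab_width slab thickness in Angstrom, default 1.
#' @return An object of class `slab_profile`: `counts` (slab x 20 matrix,
#'   whole-protein), `slab_lower` (lower edges), `residues` (pooled
#'   residue table), `totals_whole`, `totals_soluble`, `n_skipped`,
#'   `half_thickness` (mean across structures).
#' @export
build_slab_profile <- function(structures, slab_width = 1) {
  if (inherits(structures, "membrane_structure")) structures <- list(structures)
  if (!length(structures)) stop("no structures supplied")
  res <- do.call(rbind, lapply(structures, function(s) {
    stopifnot(inherits(s, "membrane_structure"))
    r <- s$residues
    r$half_thickness <- s$half_thickness
    r
  }))
  res$aa <- aa_one(res$resname)
  bad <- is.na(res$aa) | !is.finite(res$ca_z)
  n_skipped <- sum(bad)
  res <- res[!bad, , drop = FALSE]
  if (!nrow(res)) stop("all residues skipped: no usable C-alpha records")
  res$slab <- floor(res$ca_z / slab_width)

  slabs <- seq(min(res$slab), max(res$slab))
  counts <- matrix(0L, nrow = length(slabs), ncol = 20,
                   dimnames = list(as.character(slabs), AA1))
  tab <- table(factor(res$slab, levels = slabs),
               factor(res$aa, levels = AA1))
  counts[] <- as.integer(tab)

  sol <- res[res$region != "TM", , drop = FALSE]
  totals_whole <- colSums(counts)
  totals_soluble <- table(factor(sol$aa, levels = AA1))
  structure(list(counts = counts, slab_lower = slabs * slab_width,
                 slab_width = slab_width, residues = res,
                 totals_whole = totals_whole,
                 totals_soluble = as.numeric(totals_soluble),
                 n_skipped = n_skipped,
                 half_thickness = mean(vapply(structures,
                   function(s) s$half_thickness, numeric(1)))),
            class = "slab_profile")
}

#' Per-slab amino-acid enrichment with separate 2/3 sigma thresholds
#'
#' For each slab s and amino acid r the enrichment is the log2 ratio of
#' the observed count to the count expected under the background
#' composition, both regularized with a pseudocount:
#' \deqn{E(s,r) = \log_2 \frac{c_{sr}+pc}{n_s \, q_r + pc}, \qquad
#'       q_r = \frac{b_r+pc}{B+20pc}}
#' (Regularizing the expectation rather than both frequencies keeps
#' zero-count cells in sparsely populated slabs on the depletion side,
#' where they belong, instead of inflating them.)
#' The background is either the total amino-acid content of the pooled
#' proteins (`whole_protein`) or the content of their soluble regions
#' only (`soluble_only`), in which case transmembrane residues are
#' excluded from the slabs as well — the mode in which the positive
#' patch emerges, since TM-biased composition otherwise skews the
#' statistics. Significance thresholds are computed separately for
#' enrichment and depletion as the standard deviations of the positive
#' and negative enrichment values (over cells within `sigma_window`
#' Angstrom of the membrane centre, so sparse far-field slabs do not
#' dominate). Slabs with no assigned residues are NA, never 0.
#'
#' @param profile a [build_slab_profile()] result.
#' @param background `"whole_protein"` or `"soluble_only"`.
#' @param pseudocount additive regularizer, default 0.5.
#' @param sigma_window half-width (Angstrom) of the region over which the
#'   sigma thresholds are computed, default 50.
#' @return An object of class `enrichment_profile`: `enrichment` (slab x
#'   20 matrix), `slab_mid`, `sigma_enrich`, `sigma_deplete`, flag
#'   matrices `enrich2`, `enrich3`, `deplete2`, `deplete3`, plus the
#'   counts and background vectors used.
#' @export
compute_enrichment <- function(profile,
                               background = c("whole_protein", "soluble_only"),
                               pseudocount = 0.5, sigma_window = 50) {
  stopifnot(inherits(profile, "slab_profile"))
  background <- match.arg(background)
  res <- profile$residues
  if (background == "soluble_only")
    res <- res[res$region != "TM", , drop = FALSE]
  if (!nrow(res)) stop("no residues left for enrichment profile")

  slabs <- seq(min(res$slab), max(res$slab))
  counts <- matrix(0L, nrow = length(slabs), ncol = 20,
                   dimnames = list(as.character(slabs), AA1))
  tab <- table(factor(res$slab, levels = slabs), factor(res$aa, levels = AA1))
  counts[] <- as.integer(tab)
  bg <- colSums(counts)
  B <- sum(bg)
  pc <- pseudocount

  n_s <- rowSums(counts)
  bg_freq <- (bg + pc) / (B + 20 * pc)
  expected <- outer(n_s, bg_freq)
  E <- log2((counts + pc) / (expected + pc))
  E[n_s == 0, ] <- NA_real_

  w <- profile$slab_width
  slab_mid <- slabs * w + w / 2
  in_win <- abs(slab_mid) <= sigma_window
  vals <- E[in_win, , drop = FALSE]
  vals <- vals[is.finite(vals)]
  # a sigma estimated from a handful of cells is meaningless; leave the
  # threshold undefined (no calls) below 10 cells on a side
  side_sd <- function(v) if (length(v) >= 10) stats::sd(v) else NA_real_
  sigma_enrich <- side_sd(vals[vals > 0])
  sigma_deplete <- side_sd(vals[vals < 0])

  flag <- function(thr, dir) {
    if (!is.finite(thr) || thr <= 0)  # no spread on this side: no calls
      return(matrix(FALSE, nrow(E), ncol(E), dimnames = dimnames(E)))
    f <- if (dir > 0) E > thr else E < -thr
    f[!is.finite(E)] <- FALSE
    f
  }
  structure(list(enrichment = E, slab_lower = slabs * w, slab_mid = slab_mid,
                 slab_width = w,
                 sigma_enrich = sigma_enrich, sigma_deplete = sigma_deplete,
                 enrich2 = flag(2 * sigma_enrich, 1),
                 enrich3 = flag(3 * sigma_enrich, 1),
                 deplete2 = flag(2 * sigma_deplete, -1),
                 deplete3 = flag(3 * sigma_deplete, -1),
                 counts = counts, background_counts = bg,
                 background = background, pseudocount = pc,
                 half_thickness = profile$half_thickness),
            class = "enrichment_profile")
}

#' Detect the patch of external positive (PEP) residues
#'
#' Pools Lys and Arg counts per slab on the extracellular side of an
#' enrichment profile (computed with the soluble-only background, the
#' mode in which the patch emerges), computes their pooled log2
#' enrichment, and reports the maximal run of contiguous slabs whose
#' pooled enrichment exceeds twice the profile's enrichment sigma. The
#' band location is reported relative to the outer-leaflet plane at
#' `+half_thickness`; the conserved patch sits about 6-10 Angstrom above
#' that plane.
#'
#' @param ep an [compute_enrichment()] result.
#' @param half_thickness outer-leaflet plane height (Angstrom); defaults
#'   to the profile's pooled mean.
#' @param min_slabs minimal run length (slabs) for a patch call, default
#'   2: single-slab excursions above 2 sigma are expected by chance and
#'   do not constitute a band. For sequence-derived profiles, whose
#'   effective depth resolution is one residue count (~3 Angstrom) per
#'   populated slab, use `min_slabs = 1`.
#' @return list: `found`, `band_above_leaflet` (c(lo, hi), Angstrom),
#'   `band_z`, `peak_z`, `peak_enrichment`, `peak_sigma` (peak in sigma
#'   units), `n_slabs`, and the per-slab pooled table `kr`.
#' @export
detect_positive_patch <- function(ep, half_thickness = ep$half_thickness,
                                  min_slabs = 2) {
  stopifnot(inherits(ep, "enrichment_profile"))
  pc <- ep$pseudocount
  n_s <- rowSums(ep$counts)
  kr <- ep$counts[, "K"] + ep$counts[, "R"]
  bg_kr <- sum(ep$background_counts[c("K", "R")])
  B <- sum(ep$background_counts)
  q_kr <- (bg_kr + pc) / (B + 20 * pc)
  E_kr <- log2((kr + pc) / (n_s * q_kr + pc))
  E_kr[n_s == 0] <- NA_real_

  tab <- data.frame(slab_lower = ep$slab_lower, slab_mid = ep$slab_mid,
                    count_kr = kr, enrichment = E_kr)
  empty <- list(found = FALSE, band_above_leaflet = NULL, band_z = NULL,
                peak_z = NULL, peak_enrichment = NULL, peak_sigma = NULL,
                n_slabs = 0L, kr = tab)
  if (!is.finite(ep$sigma_enrich) || ep$sigma_enrich <= 0) return(empty)

  # contiguity is judged over populated extracellular slabs: slabs with
  # no residues (common in sequence mode, where pseudo-depths are
  # discrete) carry no evidence either way
  pop <- which(tab$slab_mid > 0 & is.finite(tab$enrichment))
  if (!length(pop)) return(empty)
  hit <- tab$enrichment[pop] > 2 * ep$sigma_enrich
  if (!any(hit)) return(empty)

  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_slabs)
  if (!length(runs)) return(empty)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- pop[starts[best]]; i2 <- pop[ends[best]]
  band_z <- c(tab$slab_lower[i1], tab$slab_lower[i2] + ep$slab_width)
  peak <- (i1:i2)[which.max(tab$enrichment[i1:i2])]
  list(found = TRUE,
       band_above_leaflet = band_z - half_thickness,
       band_z = band_z,
       peak_z = tab$slab_mid[peak],
       peak_enrichment = tab$enrichment[peak],
       peak_sigma = tab$enrichment[peak] / ep$sigma_enrich,
       n_slabs = ends[best] - starts[best] + 1L,
       kr = tab)
}

# offsets of loop/turn residues to the nearest TM run along each chain;
# returns data.frame(k, absz, label) for non-TM residues plus k = 0 rows
# for boundary TM residues
chain_offsets <- function(residues) {
  out <- list()
  if (!".struct" %in% names(residues)) residues$.struct <- 1L
  for (ch in unique(paste(residues$.struct, residues$chain))) {
    r <- residues[paste(residues$.struct, residues$chain) == ch, ]
    r <- r[order(r$resnum), ]
    tm <- r$region == "TM"
    if (!any(tm) || all(tm)) next
    runs <- rle(!tm)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (!runs$values[j]) next       # a TM run
      i1 <- starts[j]; i2 <- ends[j]
      has_prev <- i1 > 1L             # TM immediately before
      has_next <- i2 < nrow(r)        # TM immediately after
      if (!has_prev && !has_next) next
      pos <- seq(i1, i2)
      d_prev <- if (has_prev) pos - (i1 - 1L) else Inf
      d_next <- if (has_next) (i2 + 1L) - pos else Inf
      k <- pmin(d_prev, d_next)
      out[[length(out) + 1L]] <- data.frame(
        k = k, absz = abs(r$ca_z[pos]), side = r$side[pos])
      if (has_prev)
        out[[length(out) + 1L]] <- data.frame(
          k = 0L, absz = abs(r$ca_z[i1 - 1L]), side = r$side[i1 - 1L])
      if (has_next)
        out[[length(out) + 1L]] <- data.frame(
          k = 0L, absz = abs(r$ca_z[i2 + 1L]), side = r$side[i2 + 1L])
    }
  }
  if (!length(out)) stop("no loop/turn residues flanked by TM runs found")
  do.call(rbind, out)
}

#' Calibrate residue count against membrane distance
#'
#' From membrane-aligned structures with topology labels, builds the
#' monotone mapping from residue count k (sequence distance from the last
#' membrane-boundary residue along the chain) to the median |z| distance
#' from the membrane centre, used to place sequence-only records on the
#' depth axis. Raw per-k medians are made monotone by isotonic
#' regression; offsets with fewer than `min_obs` loop observations are
#' flagged low-confidence. k = 0 anchors at the membrane boundary.
#'
#' @param structures a `membrane_structure` or list of them.
#' @param min_obs minimal observations per offset, default 10.
#' @return An object of class `distance_calibration`: `table`
#'   (k, median_absz, fitted_absz, n, low_confidence) and `predict(k)`,
#'   which linearly interpolates and extends the last fitted segment.
#' @export
calibrate_distance <- function(structures, min_obs = 10) {
  if (inherits(structures, "membrane_structure")) structures <- list(structures)
  res <- do.call(rbind, lapply(seq_along(structures), function(i) {
    r <- structures[[i]]$residues
    r$.struct <- i
    r
  }))
  off <- chain_offsets(res)
  agg <- stats::aggregate(absz ~ k, data = off, FUN = stats::median)
  nobs <- stats::aggregate(absz ~ k, data = off, FUN = length)
  agg <- agg[order(agg$k), ]
  nobs <- nobs[order(nobs$k), ]
  iso <- stats::isoreg(agg$k, agg$absz)
  tab <- data.frame(k = agg$k, median_absz = agg$absz,
                    fitted_absz = iso$yf, n = nobs$absz,
                    low_confidence = nobs$absz < min_obs)
  pred <- function(k) {
    if (nrow(tab) == 1) return(rep(tab$fitted_absz, length(k)))
    y <- stats::approx(tab$k, tab$fitted_absz, xout = pmin(k, max(tab$k)),
                       rule = 2, ties = "ordered")$y
    # linear extension beyond the last observed offset
    over <- k > max(tab$k)
    if (any(over)) {
      m <- nrow(tab)
      slope <- (tab$fitted_absz[m] - tab$fitted_absz[m - 1]) /
        (tab$k[m] - tab$k[m - 1])
      y[over] <- tab$fitted_absz[m] + slope * (k[over] - max(tab$k))
    }
    y
  }
  structure(list(table = tab, predict = pred), class = "distance_calibration")
}

# split a topology string into runs; returns data.frame(label, start, end)
topology_runs <- function(topology) {
  chars <- strsplit(topology, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L, end = ends,
             stringsAsFactors = FALSE)
}

#' Place a topology-annotated sequence on the membrane depth axis
#'
#' Assigns each residue of a sequence with per-residue topology labels
#' (S strand-TM, L extracellular loop, T periplasmic turn, X soluble) a
#' pseudo z coordinate: loop/turn residues map their residue count from
#' the nearer strand boundary through the distance calibration, signed by
#' side (L positive, T negative; X inherits the sign of its adjacent
#' membrane-flanking run); strand residues interpolate linearly across
#' the membrane between -h and +h following the strand direction.
#'
#' @param sequence 1-letter amino-acid string.
#' @param topology same-length string over S/L/T/X.
#' @param calibration a [calibrate_distance()] result.
#' @param half_thickness half bilayer thickness (Angstrom).
#' @return data.frame with columns `resname`, `chain`, `resnum`, `ca_z`,
#'   `region`, `side` suitable for [membrane_structure()].
#' @export
sequence_to_depth <- function(sequence, topology, calibration,
                              half_thickness) {
  stopifnot(inherits(calibration, "distance_calibration"))
  seq_chars <- strsplit(sequence, "")[[1]]
  top_chars <- strsplit(topology, "")[[1]]
  if (length(seq_chars) != length(top_chars))
    stop("sequence and topology must have equal length")
  bad <- !top_chars %in% c("S", "L", "T", "X")
  if (any(bad))
    stop("unlabelled or unknown topology characters at positions ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  n <- length(seq_chars)
  z <- rep(NA_real_, n)
  runs <- topology_runs(topology)
  h <- half_thickness

  side_of <- function(label, i_run) {
    if (label == "L") return(1)
    if (label == "T") return(-1)
    # X: side of the adjacent L/T run, periplasmic by default
    for (j in c(i_run - 1L, i_run + 1L)) {
      if (j >= 1 && j <= nrow(runs) && runs$label[j] %in% c("L", "T"))
        return(if (runs$label[j] == "L") 1 else -1)
    }
    -1
  }

  for (i in seq_len(nrow(runs))) {
    lab <- runs$label[i]
    pos <- seq(runs$start[i], runs$end[i])
    len <- length(pos)
    if (lab == "S") {
      # direction: towards the following loop side (up if next is L/ext)
      nxt <- if (i < nrow(runs)) runs$label[i + 1] else NA
      prv <- if (i > 1) runs$label[i - 1] else NA
      up <- if (!is.na(nxt)) nxt %in% c("L") else !(prv %in% c("L"))
      zz <- seq(-h, h, length.out = max(len, 2))[seq_len(len)]
      z[pos] <- if (up) zz else -zz
    } else {
      sgn <- side_of(lab, i)
      has_prev <- runs$start[i] > 1 && top_chars[runs$start[i] - 1L] == "S"
      has_next <- runs$end[i] < n && top_chars[runs$end[i] + 1L] == "S"
      kk <- seq_len(len)
      d_prev <- if (has_prev) kk else Inf
      d_next <- if (has_next) rev(kk) else Inf
      k <- pmin(d_prev, d_next)
      if (all(!is.finite(k))) k <- kk   # soluble tail with no flanking strand
      z[pos] <- sgn * calibration$predict(k)
    }
  }
  data.frame(resname = seq_chars, chain = "A", resnum = seq_len(n),
             ca_z = z,
             region = ifelse(top_chars == "S", "TM", "soluble"),
             side = ifelse(top_chars == "S", "membrane",
                           ifelse(z > 0, "extracellular", "periplasmic")),
             stringsAsFactors = FALSE)
}

#' Sequence-mode enrichment profile
#'
#' Runs the slab-enrichment analysis on topology-annotated sequences by
#' mapping each record onto pseudo depths (see [sequence_to_depth()])
#' and then applying [build_slab_profile()] and [compute_enrichment()]
#' exactly as in structure mode.
#'
#' @param records list of records, each a list with `sequence` and
#'   `topology` strings.
#' @param calibration a [calibrate_distance()] result.
#' @param half_thickness half bilayer thickness (Angstrom).
#' @param background,pseudocount passed to [compute_enrichment()].
#' @return an `enrichment_profile`.
#' @export
sequence_enrichment <- function(records, calibration, half_thickness,
                                background = "soluble_only",
                                pseudocount = 0.5) {
  if (!length(records)) stop("no sequence records supplied")
  structs <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    res <- tryCatch(
      sequence_to_depth(rec$sequence, rec$topology, calibration,
                        half_thickness),
      error = function(e) stop("record ", i, ": ", conditionMessage(e)))
    membrane_structure(res, half_thickness)
  })
  profile <- build_slab_profile(structs)
  compute_enrichment(profile, background = background,
                     pseudocount = pseudocount)
}
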