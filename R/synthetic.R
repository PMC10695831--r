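# Synthetic-data generators with known ground truth for every input
# class: zeta training tables, kinetic/titration/laurdan/spectral curves,
# membrane-aligned barrel cohorts with plantable Lys/Arg patches, and
# bead trajectories with a plantable lipid-binding site.

#' Named presets mirroring the headline study systems
#'
#' Read-only registry of generator presets whose truth parameters are
#' anchored to the headline measured quantities: OmpA folds into DMPC
#' liposomes with k_obs ~5e-4 s^-1 and into DMPG more than 40-fold
#' faster (the DMPG preset uses 44-fold, 0.022 s^-1); urea midpoints P_m
#' of 4.5 M (DMPG) and 2.3 M (DMPC); laurdan melting midpoints of 24
#' (DMPC) and 23 (DMPG) degrees C. The two-phase preset emulates the
#' biphasic traces seen with DMPS-containing liposomes; its rate pair is
#' an invented but representative choice.
#'
#' @return named list of preset definitions (kind, truth, defaults).
#' @export
asymfold_presets <- function() {
  list(
    `s-DMPC-folding` = list(
      kind = "kinetics", k_obs = 5e-4, F0 = 0.2, amplitude = 1.0,
      t_max = 15 * 3600, n_points = 400, noise = 0.01, tolerance = 0.05),
    `s-DMPG-folding` = list(
      kind = "kinetics", k_obs = 44 * 5e-4, F0 = 0.2, amplitude = 1.0,
      t_max = 300, n_points = 400, noise = 0.01, tolerance = 0.05),
    `s-DMPS-folding-2phase` = list(
      kind = "kinetics", k_obs = c(1e-2, 5e-4), F0 = 0.2,
      amplitude = c(0.5, 0.5), t_max = 15 * 3600, n_points = 400,
      noise = 0.005, tolerance = 0.10),
    `s-DMPG-stability` = list(
      kind = "titration", Pm = 4.5, s = 0.3, upper = 0.95, lower = 0.05,
      urea = seq(0, 8, by = 0.5), noise = 0.03, tolerance = 0.15),
    `s-DMPC-stability` = list(
      kind = "titration", Pm = 2.3, s = 0.3, upper = 0.95, lower = 0.05,
      urea = seq(0, 8, by = 0.5), noise = 0.03, tolerance = 0.15),
    DMPC = list(
      kind = "laurdan", tm = 24, gp_gel = 0.55, gp_fluid = -0.05,
      width = 0.8, temp = seq(14, 34, by = 0.25), noise = 0.002,
      tolerance = 0.25),
    DMPG = list(
      kind = "laurdan", tm = 23, gp_gel = 0.55, gp_fluid = -0.05,
      width = 0.8, temp = seq(13, 33, by = 0.25), noise = 0.002,
      tolerance = 0.25),
    `liposome-rhodamine` = list(
      kind = "spectrum", components = c(liposome = 1.5, fluorophore = 0.3),
      noise = 1e-4, tolerance = 0.02)
  )
}

get_preset <- function(name) {
  p <- asymfold_presets()[[name]]
  if (is.null(p)) stop("unknown preset '", name, "'; see asymfold_presets()")
  p
}

# built-in reference spectral shapes on a 300-600 nm grid:
# liposome scattering ~ lambda^-4, fluorophore ~ Gaussian band at 560 nm
reference_spectra <- function(wavelengths = seq(300, 600, by = 2)) {
  lip <- (wavelengths / 300)^-4
  fluo <- exp(-(wavelengths - 560)^2 / (2 * 18^2))
  list(
    liposome = data.frame(wavelength_nm = wavelengths, absorbance = lip),
    fluorophore = data.frame(wavelength_nm = wavelengths, absorbance = fluo)
  )
}

#' Generate a synthetic curve with known truth
#'
#' Generates one curve of the requested kind, either from a named preset
#' (see [asymfold_presets()]) or from explicitly supplied truth
#' parameters, with Gaussian noise:
#' * `kinetics`: F(t) = F0 + sum_i A_i (1 - exp(-k_i t)) on a uniform
#'   time grid; `noise` is relative to the total amplitude.
#' * `titration`: 4-parameter logistic folded fraction versus urea;
#'   `noise` is absolute in fraction units.
#' * `laurdan`: logistic GP(T) falling from `gp_gel` to `gp_fluid`
#'   around the melting midpoint; `noise` is absolute in GP units.
#' * `spectrum`: non-negative mixture of the built-in liposome and
#'   fluorophore reference shapes.
#'
#' @param kind one of "kinetics", "titration", "laurdan", "spectrum".
#' @param preset preset name, or `NULL` with `truth` supplied.
#' @param truth named list of generator parameters overriding or
#'   replacing the preset.
#' @param noise noise level; defaults to the preset's.
#' @param seed RNG seed; identical seeds give identical curves.
#' @return list with `data` (a data.frame in the module's CSV column
#'   convention), `truth` and `kind`.
#' @export
#' @examples
#' curve <- gen_curves("titration", preset = "s-DMPG-stability", seed = 1)
#' head(curve$data)
gen_curves <- function(kind = c("kinetics", "titration", "laurdan",
                                "spectrum"),
                       preset = NULL, truth = list(), noise = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  p <- if (!is.null(preset)) get_preset(preset) else list(kind = kind)
  if (p$kind != kind) stop("preset '", preset, "' is of kind '", p$kind, "'")
  p[names(truth)] <- truth
  if (!is.null(noise)) p$noise <- noise
  if (is.null(p$noise)) stop("noise level neither in preset nor supplied")
  if (p$noise < 0) stop("noise sd must be non-negative")
  set.seed(seed)

  if (kind == "kinetics") {
    t <- seq(0, p$t_max, length.out = p$n_points)
    clean <- p$F0 + Reduce(`+`, Map(function(A, k) A * (1 - exp(-k * t)),
                                    p$amplitude, p$k_obs))
    sd_abs <- p$noise * sum(p$amplitude)
    data <- data.frame(time_s = t,
                       signal = clean + stats::rnorm(length(t), 0, sd_abs))
  } else if (kind == "titration") {
    u <- p$urea
    clean <- p$lower + (p$upper - p$lower) / (1 + exp((u - p$Pm) / p$s))
    data <- data.frame(urea_M = u,
                       fraction_folded = clean +
                         stats::rnorm(length(u), 0, p$noise))
  } else if (kind == "laurdan") {
    temp <- p$temp
    gp <- p$gp_fluid + (p$gp_gel - p$gp_fluid) /
      (1 + exp((temp - p$tm) / p$width))
    gp <- gp + stats::rnorm(length(temp), 0, p$noise)
    # back out intensities consistent with the GP definition
    I_total <- 1
    data <- data.frame(temp_C = temp,
                       I440 = I_total * (1 + gp) / 2,
                       I490 = I_total * (1 - gp) / 2)
    data$gp <- gp_value(data$I440, data$I490)
  } else {
    refs <- reference_spectra()
    comps <- p$components
    mix <- Reduce(`+`, Map(function(nm, sc) sc * refs[[nm]]$absorbance,
                           names(comps), comps))
    lam <- refs[[1]]$wavelength_nm
    data <- data.frame(wavelength_nm = lam,
                       absorbance = mix +
                         stats::rnorm(length(lam), 0, p$noise))
  }
  list(data = data, truth = p, kind = kind, preset = preset, seed = seed)
}

#' Generate a synthetic zeta-potential training table
#'
#' Draws the eight model features from realistic ranges (monovalent salt
#' 0-0.5 M, divalent 0-0.02 M, pH 3-10, hydrodynamic radius 40-120 nm,
#' temperature 10-40 C, mean lipid charge -1 to +1, mean Tm -20-60 C,
#' cholesterol fraction 0-0.5) and plants a known linear effect
#' structure, by default charge-dominant at 30 mV per elementary charge
#' so that a fully charged (PG-like) composition sits near -30 mV.
#' Measurement noise is homoscedastic with `noise_sd` when given;
#' otherwise each row draws its own sd from `sd_range` (heteroscedastic
#' measurement error). The per-row sd is reported as `zeta_sd_mV`.
#'
#' @param n number of rows (>= 20), default 315 as in the compiled
#'   literature table.
#' @param effects named list of linear coefficients over the feature
#'   names; an all-zero spec is allowed but flagged with a warning.
#' @param noise_sd homoscedastic noise sd (mV) or `NULL`.
#' @param sd_range heteroscedastic per-row sd range (mV).
#' @param seed RNG seed.
#' @return list with `table` (training data.frame) and `truth`
#'   (coefficients and the generating function).
#' @export
gen_zeta_table <- function(n = 315, effects = list(mean_charge = 30),
                           noise_sd = NULL, sd_range = c(0.5, 1.5),
                           seed = 1L) {
  if (n < 20) stop("need n >= 20")
  if (all(unlist(effects) == 0))
    warning("degenerate effect spec: all coefficients zero")
  set.seed(seed)
  tab <- data.frame(
    salt_mono_M = stats::runif(n, 0, 0.5),
    salt_di_M = stats::runif(n, 0, 0.02),
    pH = stats::runif(n, 3, 10),
    rh_nm = stats::runif(n, 40, 120),
    temp_C = stats::runif(n, 10, 40),
    mean_charge = stats::runif(n, -1, 1),
    mean_tm_C = stats::runif(n, -20, 60),
    chol_frac = stats::runif(n, 0, 0.5)
  )
  coef <- setNames(rep(0, length(zeta_feature_names())), zeta_feature_names())
  unknown <- setdiff(names(effects), names(coef))
  if (length(unknown)) stop("unknown features in effect spec: ",
                            paste(unknown, collapse = ", "))
  coef[names(effects)] <- unlist(effects)
  truth_fun <- function(df) as.matrix(df[, names(coef)]) %*% coef
  clean <- as.numeric(truth_fun(tab))
  sd_row <- if (is.null(noise_sd)) stats::runif(n, sd_range[1], sd_range[2])
            else rep(noise_sd, n)
  tab$zeta_mV <- clean + stats::rnorm(n, 0, sd_row)
  tab$zeta_sd_mV <- sd_row
  list(table = tab,
       truth = list(coefficients = coef, generating = truth_fun,
                    noise_sd = noise_sd, sd_range = sd_range, seed = seed))
}

# idealized-barrel geometry constants (Angstrom per residue along z)
BARREL_RISE <- 3

# hydrophobic-biased composition for TM strand residues
tm_aa_probs <- function() {
  p <- setNames(rep(1, 20), AA1)
  p[c("L", "I", "V", "F", "A", "G", "W", "Y")] <- 4
  p / sum(p)
}

#' Generate a cohort of idealized membrane-aligned beta-barrels
#'
#' Builds `n_structures` idealized barrels: even numbers of TM strands
#' spanning the membrane (hydrophobic-biased composition), extracellular
#' loops arcing above the outer leaflet at ~3 Angstrom per residue, and
#' short periplasmic turns. Loop/turn composition is uniform over the 20
#' amino acids except inside the planted band, where the Lys/Arg
#' probability is multiplied by `patch$excess`. Matched
#' topology-annotated sequence records (S/L/T per residue) are derived
#' from the same chains, sharing the ground truth.
#'
#' @param n_structures number of barrels, default 75 (matching the size
#'   of a clustered experimental-structure cohort).
#' @param n_strands strands per barrel, even, >= 8.
#' @param half_thickness half bilayer thickness (Angstrom), default 15.
#' @param loop_len_range,turn_len_range inclusive length ranges for
#'   extracellular loops and periplasmic turns.
#' @param patch list with `centre` (Angstrom above the outer leaflet),
#'   `width` (Angstrom) and `excess` (K/R probability multiplier; 1
#'   plants nothing). `NULL` for a null cohort.
#' @param seed RNG seed.
#' @return list with `structures` (list of [membrane_structure()]),
#'   `records` (matched sequence/topology records) and `truth`.
#' @export
gen_membrane_cohort <- function(n_structures = 75, n_strands = 8,
                                half_thickness = 15,
                                loop_len_range = c(6, 14),
                                turn_len_range = c(2, 5),
                                patch = list(centre = 8, width = 4,
                                             excess = 3),
                                seed = 1L) {
  if (n_strands < 8 || n_strands %% 2 != 0)
    stop("'n_strands' must be even and >= 8")
  h <- half_thickness
  max_reach <- BARREL_RISE * ceiling(max(loop_len_range) / 2)
  if (!is.null(patch) && patch$excess != 1 &&
      patch$centre + patch$width / 2 > max_reach)
    stop("patch band lies beyond the modelled loop reach (",
         max_reach, " Angstrom above the leaflet)")
  band <- if (!is.null(patch))
    h + patch$centre + c(-1, 1) * patch$width / 2 else c(NA, NA)
  excess <- if (!is.null(patch)) patch$excess else 1

  set.seed(seed)
  p_tm <- tm_aa_probs()
  p_loop <- setNames(rep(1 / 20, 20), AA1)
  p_patch <- p_loop
  p_patch[c("K", "R")] <- p_patch[c("K", "R")] * excess
  p_patch <- p_patch / sum(p_patch)
  n_tm <- ceiling(2 * h / BARREL_RISE) + 1

  sample_aa <- function(n, probs) sample(AA1, n, replace = TRUE, prob = probs)

  structures <- vector("list", n_structures)
  records <- vector("list", n_structures)
  for (si in seq_len(n_structures)) {
    z <- numeric(0); top <- character(0); aa <- character(0)
    for (st in seq_len(n_strands)) {
      up <- st %% 2 == 1
      zz <- seq(-h, h, length.out = n_tm)
      if (!up) zz <- rev(zz)
      z <- c(z, zz); top <- c(top, rep("S", n_tm))
      aa <- c(aa, sample_aa(n_tm, p_tm))
      if (st < n_strands) {
        if (up) {   # extracellular loop arcs above +h
          len <- sample(loop_len_range[1]:loop_len_range[2], 1)
          rise <- ceiling(len / 2)
          path <- c(seq_len(rise), rev(seq_len(len - rise)))
          zz <- h + BARREL_RISE * path + stats::rnorm(len, 0, 1)
          zz <- pmax(zz, h + 0.5)
          top <- c(top, rep("L", len))
        } else {    # periplasmic turn below -h
          len <- sample(turn_len_range[1]:turn_len_range[2], 1)
          rise <- ceiling(len / 2)
          path <- c(seq_len(rise), rev(seq_len(len - rise)))
          zz <- -h - BARREL_RISE * path - stats::rnorm(len, 0, 1)
          zz <- pmin(zz, -h - 0.5)
          top <- c(top, rep("T", len))
        }
        in_band <- !is.na(band[1]) & top[length(top) - length(zz) + 1] == "L" &
          zz >= band[1] & zz < band[2]
        aa <- c(aa, ifelse(in_band,
                           sample_aa(length(zz), p_patch),
                           sample_aa(length(zz), p_loop)))
        z <- c(z, zz)
      }
    }
    res <- data.frame(resname = aa, chain = "A", resnum = seq_along(aa),
                      ca_z = z,
                      region = ifelse(top == "S", "TM", "soluble"),
                      side = ifelse(top == "S", "membrane",
                                    ifelse(z > 0, "extracellular",
                                           "periplasmic")),
                      stringsAsFactors = FALSE)
    structures[[si]] <- membrane_structure(res, h)
    records[[si]] <- list(sequence = paste(aa, collapse = ""),
                          topology = paste(top, collapse = ""))
  }
  list(structures = structures, records = records,
       truth = list(patch = patch, band_z = band,
                    band_above_leaflet = if (!is.null(patch))
                      band - h else NULL,
                    half_thickness = h, n_strands = n_strands,
                    seed = seed))
}

#' Generate a bead trajectory with a plantable lipid-binding site
#'
#' Builds a trajectory whose protein is a small cluster of single-bead
#' residues at the box centre; `n_binders` designated lipids follow
#' independent two-state (telegraph) processes with stationary bound
#' fraction `f`: in the bound state a binder sits uniformly within the
#' short occupancy cutoff of the site, in the unbound state uniformly in
#' the box but outside an exclusion shell beyond the long cutoff.
#' Background lipids stay outside the exclusion shell throughout, so
#' the planted bound fraction is recoverable from occupancy analysis.
#'
#' @param n_frames number of frames.
#' @param f planted stationary bound fraction in [0, 1].
#' @param n_binders number of designated binder lipids, default 1.
#' @param n_lipids named vector of total lipid counts per species;
#'   binders are taken from the first species.
#' @param box orthorhombic box lengths (nm), default c(10, 10, 10).
#' @param persistence mean bound-dwell length in frames, default 3.
#' @param cfg a [contact_config()] supplying the cutoffs.
#' @param seed RNG seed.
#' @return list with `trajectory`, `site` (residue ids) and `truth`.
#' @export
gen_trajectory <- function(n_frames = 1000, f = 0.4, n_binders = 1,
                           n_lipids = c(DMPG = 4, DMPC = 8),
                           box = c(10, 10, 10), persistence = 3,
                           cfg = contact_config(), seed = 1L) {
  if (f < 0 || f > 1) stop("'f' must lie in [0, 1]")
  site_radius <- 0.25
  # unbound lipids stay farther than the long cutoff from every site bead
  exclusion <- cfg$occupancy_cutoff_long + site_radius + 0.15
  if (any(box / 2 <= exclusion + 0.2))
    stop("box too small to place unbound lipids beyond the long cutoff")
  set.seed(seed)
  centre <- box / 2
  # 3 single-bead site residues in a tight triangle at the box centre
  prot <- data.frame(residue = 1:3,
                     x = centre[1] + c(0, 0.2, -0.2),
                     y = centre[2] + c(0.2, -0.1, -0.1),
                     z = centre[3])
  species1 <- names(n_lipids)[1]
  if (n_binders > n_lipids[1])
    stop("'n_binders' exceeds the count of the first species")

  bead1 <- c(prot$x[1], prot$y[1], prot$z[1])
  rand_sphere <- function(r_lo, r_hi) {
    r <- stats::runif(1, r_lo, r_hi)
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    bead1 + r * v
  }
  rand_far <- function() {
    repeat {
      pos <- stats::runif(3) * box
      if (sqrt(sum((pos - centre)^2)) > exclusion) return(pos)
    }
  }

  # telegraph transition probabilities with stationary bound fraction f
  p_bu <- if (f >= 1) 0 else 1 / persistence
  p_ub <- if (f >= 1) 1 else if (f <= 0) 0 else
    p_bu * f / (1 - f)
  states <- matrix(FALSE, n_frames, n_binders)
  for (bi in seq_len(n_binders)) {
    s <- stats::runif(1) < f
    for (fr in seq_len(n_frames)) {
      states[fr, bi] <- s
      s <- if (s) stats::runif(1) >= p_bu else stats::runif(1) < p_ub
    }
  }

  lip_ids <- unlist(lapply(seq_along(n_lipids), function(i)
    paste0(names(n_lipids)[i], "_", seq_len(n_lipids[i]))))
  lip_species <- rep(names(n_lipids), n_lipids)
  frames <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    pos <- matrix(0, length(lip_ids), 3)
    for (li in seq_along(lip_ids)) {
      if (lip_species[li] == species1 && li <= n_binders) {
        pos[li, ] <- if (states[fr, li])
          rand_sphere(0.1, cfg$occupancy_cutoff_short - 0.02)
        else rand_far()
      } else {
        pos[li, ] <- rand_far()
      }
    }
    frames[[fr]] <- list(
      protein = prot,
      lipids = data.frame(mol = lip_ids, species = lip_species,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  }
  list(trajectory = trajectory(frames, box = box),
       site = prot$residue,
       truth = list(f = f, n_binders = n_binders, persistence = persistence,
                    bound_any = mean(apply(states, 1, any)), seed = seed))
}
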