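test_that("contact counting respects the 0.55 nm cutoff", {
  traj <- trajectory(list(frame_at_distance(0.50)))
  expect_equal(unname(contact_counts(traj)["1", "DMPG"]), 1L)
  traj2 <- trajectory(list(frame_at_distance(0.60)))
  expect_equal(unname(contact_counts(traj2)["1", "DMPG"]), 0L)
})

test_that("minimum-image convention wraps contacts across the box", {
  # raw separation 9.9 nm in a 10 nm box is 0.1 nm by minimum image
  fr <- list(protein = data.frame(residue = 1, x = 0.05, y = 5, z = 5),
             lipids = data.frame(mol = "L1", species = "DMPG",
                                 x = 9.95, y = 5, z = 5))
  traj <- trajectory(list(fr), box = c(10, 10, 10))
  expect_equal(unname(contact_counts(traj)["1", "DMPG"]), 1L)
  # without periodicity the same geometry is not a contact
  expect_equal(unname(contact_counts(trajectory(list(fr)))["1", "DMPG"]), 0L)
  expect_error(trajectory(list(fr), box = diag(3)), "triclinic")
})

test_that("contact counts match a brute-force all-pairs oracle", {
  set.seed(6)
  for (rep in 1:5) {
    frames <- lapply(1:3, function(i) {
      list(protein = data.frame(residue = rep(1:2, each = 2),
                                x = runif(4, 0, 3), y = runif(4, 0, 3),
                                z = runif(4, 0, 3)),
           lipids = data.frame(mol = rep(c("a", "b", "c"), each = 2),
                               species = rep(c("DMPG", "DMPG", "DMPC"),
                                             each = 2),
                               x = runif(6, 0, 3), y = runif(6, 0, 3),
                               z = runif(6, 0, 3)))
    })
    traj <- trajectory(frames, box = c(3, 3, 3))
    expect_equal(contact_counts(traj),
                 brute_contacts(traj, 0.55))
  }
})

test_that("contact counts are invariant to frame order", {
  set.seed(7)
  frames <- lapply(1:4, function(i)
    list(protein = data.frame(residue = 1, x = runif(1, 0, 2), y = 1, z = 1),
         lipids = data.frame(mol = "L1", species = "DMPG",
                             x = runif(1, 0, 2), y = 1, z = 1)))
  c1 <- contact_counts(trajectory(frames))
  c2 <- contact_counts(trajectory(rev(frames)))
  expect_equal(c1, c2)
})

test_that("normalization divides by lipid count and frame number", {
  raw <- matrix(c(100L, 100L), 1, 2,
                dimnames = list("1", c("DMPG", "DMPC")))
  prof <- normalize_contacts(raw, c(DMPG = 50, DMPC = 100), n_frames = 10)
  expect_equal(unname(prof$normalized[1, "DMPG"]), 0.2)
  # 2x more abundant species, same raw count -> half the normalized value
  expect_equal(unname(prof$normalized[1, "DMPC"]), 0.1)
  expect_warning(normalize_contacts(raw, c(DMPG = 0, DMPC = 100), 10),
                 "zero lipids")
})

test_that("occupancy follows the dual-cutoff hysteresis rule", {
  # permanently bound lipid
  traj <- trajectory(lapply(1:10, function(i) frame_at_distance(0.4)))
  expect_equal(site_occupancy(traj, 1, "DMPG"), 1.0)

  # enters at 0.4 then oscillates 0.5/0.7: never exceeds 0.8, stays bound
  d <- c(0.4, rep(c(0.5, 0.7), 5))
  traj2 <- trajectory(lapply(d, frame_at_distance))
  expect_equal(site_occupancy(traj2, 1, "DMPG"), 1.0)

  # the same oscillation without the initial entry never binds
  traj3 <- trajectory(lapply(d[-1], frame_at_distance))
  expect_equal(site_occupancy(traj3, 1, "DMPG"), 0.0)

  # always far
  traj4 <- trajectory(lapply(rep(1.2, 6), frame_at_distance))
  expect_equal(site_occupancy(traj4, 1, "DMPG"), 0.0)

  # leaving past the long cutoff ends the bound interval
  traj5 <- trajectory(lapply(c(0.4, 0.9, 0.6), frame_at_distance))
  expect_equal(site_occupancy(traj5, 1, "DMPG"), 1 / 3)

  expect_error(site_occupancy(traj, 99, "DMPG"), "99")
})

test_that("occupancy is monotone in both cutoffs", {
  set.seed(8)
  d <- runif(200, 0.3, 1.0)
  traj <- trajectory(lapply(d, frame_at_distance))
  occ <- function(short, long)
    site_occupancy(traj, 1, "DMPG",
                   contact_config(occupancy_cutoff_short = short,
                                  occupancy_cutoff_long = long))
  expect_lte(occ(0.475, 0.6), occ(0.475, 0.8))
  expect_lte(occ(0.40, 0.8), occ(0.55, 0.8))
})
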