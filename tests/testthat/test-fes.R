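rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

test_that("radius of gyration matches closed forms and brute force", {
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two, selection = NULL), 1.5)
  same <- matrix(1, 5, 3)
  expect_equal(radius_of_gyration(same, selection = NULL), 0)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(2.5 * cos(ang), 2.5 * sin(ang), 0)
  expect_equal(radius_of_gyration(ring, selection = NULL), 2.5)
  # brute force centroid computation
  set.seed(1)
  x <- matrix(stats::rnorm(30), 10, 3)
  ctr <- colMeans(x)
  brute <- sqrt(mean(apply(x, 1, function(r) sum((r - ctr)^2))))
  expect_equal(radius_of_gyration(x, selection = NULL), brute)
  expect_error(radius_of_gyration(two[1, , drop = FALSE], NULL), "2 atoms")
})

test_that("superposition RMSD is zero under rigid motion and matches the 2-point closed form", {
  h <- ideal_helix(8)
  expect_equal(rmsd_to_reference(h, h), 0)
  moved <- h %*% t(rot_z(0.7))
  moved <- sweep(moved, 2, c(1, -2, 3), `+`)
  attributes(moved)[c("atom", "residue_index")] <-
    attributes(h)[c("atom", "residue_index")]
  expect_lt(rmsd_to_reference(moved, h), 1e-9)

  # two-point closed form: |d1 - d2| / 2
  a <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  b <- matrix(c(0, 0, 0, 0, 5, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd_to_reference(a, b, selection = NULL), 1.5)
})

test_that("RMSD and Rg agree with the bio3d reference implementation", {
  set.seed(7)
  x <- matrix(stats::rnorm(36), 12, 3)
  y <- matrix(stats::rnorm(36), 12, 3)
  ours <- rmsd_to_reference(x, y, selection = NULL)
  theirs <- bio3d::rmsd(as.numeric(t(y)), as.numeric(t(x)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 dp
  expect_equal(radius_of_gyration(x, selection = NULL),
               bio3d::rgyr(xyz = as.numeric(t(x)),
                           mass = rep(1, 12)), tolerance = 1e-6)
})

test_that("backbone dihedrals agree with the bio3d torsion routine", {
  h <- build_backbone(c(-70, -60, -120, -65, -80), c(-40, -45, 140, -30, 150))
  d <- backbone_dihedrals(h)
  for (i in 2:4) {
    at <- function(j, k) h[3 * (j - 1) + k, ]
    ref <- bio3d::torsion.xyz(c(at(i - 1, 3), at(i, 1), at(i, 2), at(i, 3)))
    expect_equal(d$phi[i], as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("the FES is a shifted negative-log population with unsampled markers", {
  # two clusters, 90/10: FES gap is ln(9)
  compact <- ideal_helix(6)
  extended <- build_backbone(rep(-135, 6), rep(135, 6))
  frames <- c(rep(list(compact), 90), rep(list(extended), 10))
  ens <- list(frames = frames, reference = compact)
  fes <- suppressWarnings(build_fes(ens, n_bins_rmsd = 5, n_bins_rg = 5))
  occ <- which(!is.na(fes$free_energy))
  expect_equal(sum(fes$populations), 1)
  expect_equal(min(fes$free_energy[occ]), 0)
  expect_equal(sort(fes$free_energy[occ]), c(0, log(9)))
  expect_true(all(is.na(fes$free_energy[-occ])))

  # uniform occupancy over 3 well-separated conformations: flat surface at 0
  stick <- function(d) matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE)
  k_frames <- rep(lapply(c(1.2, 1.4, 1.6), stick), each = 4)
  ens2 <- list(frames = k_frames, reference = stick(1))
  f2 <- suppressWarnings(build_fes(ens2, n_bins_rmsd = 3, n_bins_rg = 3))
  expect_true(all(f2$free_energy[!is.na(f2$free_energy)] == 0))
})

test_that("the FES uses population, not count, semantics and is rigid-motion invariant", {
  en <- generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 0.5), seed = 12), 150, 6)
  fes1 <- build_fes(en, n_bins_rmsd = 8, n_bins_rg = 8)
  dup <- en; dup$frames <- c(en$frames, en$frames)
  fes2 <- build_fes(dup, n_bins_rmsd = 8, n_bins_rg = 8)
  expect_equal(fes2$free_energy, fes1$free_energy)

  rot <- en
  rot$frames <- lapply(en$frames, function(f) {
    g <- sweep(f %*% t(rot_z(1.1)), 2, c(5, 5, 5), `+`)
    attributes(g)[c("atom", "residue_index")] <-
      attributes(f)[c("atom", "residue_index")]
    g
  })
  fes3 <- build_fes(rot, reference = en$reference,
                    n_bins_rmsd = 8, n_bins_rg = 8)
  expect_equal(fes3$free_energy, fes1$free_energy, tolerance = 1e-9)

  # brute-force histogram recomputation
  re <- fes1$rmsd_edges; ge <- fes1$rg_edges
  cnt <- matrix(0, 8, 8)
  for (i in seq_along(fes1$rmsd)) {
    a <- min(max(findInterval(fes1$rmsd[i], re, rightmost.closed = TRUE), 1), 8)
    b <- min(max(findInterval(fes1$rg[i], ge, rightmost.closed = TRUE), 1), 8)
    cnt[a, b] <- cnt[a, b] + 1
  }
  expect_equal(fes1$populations, cnt / length(en$frames))

  # degenerate input: identical frames give a single occupied bin at 0
  one <- list(frames = rep(list(ideal_helix(5)), 120),
              reference = ideal_helix(5))
  f1 <- build_fes(one)
  expect_equal(dim(f1$free_energy), c(1, 1))
  expect_equal(f1$free_energy[1, 1], 0)
})

test_that("helix propensity classifies ideal basins and leaves termini undefined", {
  helix_ens <- generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 1), seed = 2), 10, 7)
  hp <- helix_propensity(helix_ens)
  expect_equal(unname(hp[2:6]), rep(1, 5))
  expect_true(all(is.na(hp[c(1, 7)])))

  ext <- list(frames = rep(list(build_backbone(rep(-135, 7),
                                               rep(135, 7))), 5))
  expect_equal(unname(helix_propensity(ext)[2:6]), rep(0, 5))
})

test_that("ensemble PDB and ground-truth YAML round-trip through disk", {
  en <- generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 0.5), seed = 21), 3, 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(en, pdb)
  back <- read_ensemble_pdb(pdb)
  expect_length(back$frames, 3)
  expect_equal(back$frames[[1]], en$frames[[1]], tolerance = 1e-3,
               ignore_attr = TRUE)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth_yaml(en$truth, yml)
  tr <- read_ground_truth_yaml(yml)
  expect_equal(tr$params$helix_prob, 0.5)
  expect_equal(tr$seed, 21L)
})
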