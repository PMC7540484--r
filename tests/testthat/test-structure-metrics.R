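# shared fixtures: generated once per file
ideal_frames <- ideal_gas_box(2000, 5, c(LHA = 0.6, water = 0.35,
                                         calcium = 0.05),
                              seed = 401, n_frames = 4)

test_that("ideal-gas RDF is flat at 1 beyond contact", {
  sel_A <- select_atoms(ideal_frames[[1]], species = "LHA")
  sel_B <- select_atoms(ideal_frames[[1]], species = "water")
  rdf <- radial_distribution(ideal_frames, sel_A, sel_B, bin_width = 0.05,
                             r_max = 1.6)
  inner <- rdf$bin_centers >= 0.3
  expect_true(all(abs(rdf$g[inner] - 1) < 0.05))
})

test_that("two planted particles populate only the bin containing their distance", {
  d <- 0.73
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), 4, c("a", "b"))
  rdf <- radial_distribution(fr, 1, 2, bin_width = 0.1, r_max = 1.9)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1)
  expect_true(abs(rdf$bin_centers[nz] - d) <= 0.05)
})

test_that("expected neighbour count is conserved under bin-width changes", {
  sel_A <- select_atoms(ideal_frames[[1]], species = "LHA")
  sel_B <- select_atoms(ideal_frames[[1]], species = "water")
  count_to <- function(rdf, R) {
    rho <- rdf$n_B / prod(ideal_frames[[1]]$box)
    keep <- rdf$bin_centers <= R
    sum(4 * pi * rdf$bin_centers[keep]^2 * rho * rdf$g[keep] * rdf$bin_width)
  }
  r1 <- radial_distribution(ideal_frames, sel_A, sel_B, 0.05, r_max = 1.5)
  r2 <- radial_distribution(ideal_frames, sel_A, sel_B, 0.10, r_max = 1.5)
  expect_equal(count_to(r1, 1.5), count_to(r2, 1.5), tolerance = 0.01)
})

test_that("RDF rejects r_max beyond the minimum-image range", {
  expect_error(radial_distribution(ideal_frames[[1]], 1:5, 6:10,
                                   r_max = 3.0),
               "half the smallest box edge")
})

test_that("RDF and KB are invariant under rigid periodic translation", {
  fr <- ideal_frames[[1]]
  shifted <- md_frame(sweep(fr$coordinates, 2, c(1.3, -0.7, 2.2), "+"),
                      fr$box, fr$species, fr$element_class)
  sel_A <- select_atoms(fr, species = "LHA")
  sel_B <- select_atoms(fr, species = "water")
  r1 <- radial_distribution(fr, sel_A, sel_B, 0.05, r_max = 1.5)
  r2 <- radial_distribution(shifted, sel_A, sel_B, 0.05, r_max = 1.5)
  expect_equal(r1$g, r2$g)
  expect_equal(kb_integral(r1, 1.5)$G, kb_integral(r2, 1.5)$G)
})

test_that("KB integral: closed forms and the ideal-gas limit", {
  # constant g = 1: zero excess
  centers <- seq(0.025, 1.975, by = 0.05)
  flat <- structure(list(bin_centers = centers, g = rep(1, length(centers)),
                         bin_width = 0.05, n_frames = 1, n_A = 1, n_B = 1),
                    class = "rdf_profile")
  expect_equal(kb_integral(flat, 1.5)$G, 0)
  # g = 1 + delta on [0, R] -> (4/3) pi R^3 delta, apart from the empty
  # r = 0 anchor bin of the discrete profile
  delta <- 0.3; R <- 1.5
  bumped <- structure(list(bin_centers = centers,
                           g = rep(1 + delta, length(centers)),
                           bin_width = 0.05, n_frames = 1, n_A = 1, n_B = 1),
                      class = "rdf_profile")
  expect_equal(kb_integral(bumped, R)$G, 4 / 3 * pi * R^3 * delta,
               tolerance = 0.01)
  # ideal gas: |G| below 0.05 nm^3 at the full correlation radius
  sel_A <- select_atoms(ideal_frames[[1]], species = "LHA")
  sel_B <- select_atoms(ideal_frames[[1]], species = "water")
  rdf <- radial_distribution(ideal_frames, sel_A, sel_B, 0.05, r_max = 1.6)
  expect_lt(abs(kb_integral(rdf, 1.5)$G), 0.05)
  # starred variant scales by x_A x_B
  k <- kb_integral(bumped, R)
  ks <- kb_integral(bumped, R, molar_fractions = c(0.5, 0.2), starred = TRUE)
  expect_equal(ks$G, 0.1 * k$G)
  expect_error(kb_integral(rdf, 5), "beyond the profile")
})

test_that("preferential-solvation formula matches direct evaluation", {
  v_corr <- 4 / 3 * pi * 1.5^3
  expect_equal(prefsolv_delta(0.2, 1.0, 0.5),
               0.2 * (1.0 - 0.5) / (v_corr + 0.5))
  expect_equal(prefsolv_delta(0.2, 1.0, 0.5), 0.00683, tolerance = 1e-3)
})

test_that("ideally mixed box shows no solvation preference", {
  fr <- ideal_gas_box(2000, 5, c(sorbate = 0.01, LHA = 0.59, water = 0.35,
                                 calcium = 0.05), seed = 402, n_frames = 4)
  d <- preferential_solvation(fr, "sorbate", c("LHA", "water", "calcium"))
  expect_true(all(abs(d) < 0.02))
})

test_that("clustered boxes recover the planted preference signs", {
  fr_w <- clustered_mixture_box(seed = 403, sorbate_placement = "water_patch",
                                n_frames = 3)
  d_w <- preferential_solvation(fr_w, "sorbate", c("LHA", "water", "calcium"))
  expect_gt(d_w["water"], 0)
  expect_lt(d_w["LHA"], 0)

  fr_l <- clustered_mixture_box(seed = 404, sorbate_placement = "LHA_patch",
                                n_frames = 3)
  d_l <- preferential_solvation(fr_l, "sorbate", c("LHA", "water", "calcium"))
  expect_gt(d_l["LHA"], 0)
  expect_lt(d_l["water"], 0)
})

test_that("preferential solvation is invariant to relabeling within a species", {
  fr <- clustered_mixture_box(seed = 405, n_frames = 1)
  d1 <- preferential_solvation(fr, "sorbate", c("LHA", "water"))
  # permute the storage order of the water particles
  idx <- seq_len(nrow(fr$coordinates))
  w <- which(fr$species == "water")
  set.seed(1); idx[w] <- sample(w)
  fr2 <- md_frame(fr$coordinates[idx, ], fr$box, fr$species[idx],
                  fr$element_class[idx])
  d2 <- preferential_solvation(fr2, "sorbate", c("LHA", "water"))
  expect_equal(d1, d2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hydrogen-bond criterion boundaries are inclusive and exact", {
  mk <- function(d_ha, angle_deg) {
    # D at (1,1,1), H 0.1 nm along +x; acceptor placed so the D-H...A angle
    # at the hydrogen is exactly angle_deg (180 = linear)
    theta <- angle_deg * pi / 180
    H <- c(1.1, 1, 1)
    dir <- cos(theta) * c(-1, 0, 0) + sin(theta) * c(0, 1, 0)  # from H->D axis
    A <- H + d_ha * dir
    md_frame(rbind(c(1, 1, 1), H, A), 5,
             c("w", "w", "w"), c("heteroatom", "hydrogen", "heteroatom"))
  }
  crit <- hbond_criterion()
  expect_equal(hydrogen_bonds(mk(0.20, 180), 1, 2, 3, crit), 1)
  expect_equal(hydrogen_bonds(mk(0.26, 180), 1, 2, 3, crit), 0)
  expect_equal(hydrogen_bonds(mk(0.20, 134), 1, 2, 3, crit), 0)
  # boundary values count
  expect_equal(hydrogen_bonds(mk(0.25, 180), 1, 2, 3, crit), 1)
  expect_equal(hydrogen_bonds(mk(0.20, 135), 1, 2, 3, crit), 1)
})

test_that("planted hydrogen-bond frames are counted exactly", {
  fr <- planted_hbond_frame(7, 4, 5, seed = 406)
  n <- hydrogen_bonds(fr, attr(fr, "donors"), attr(fr, "hydrogens"),
                      attr(fr, "acceptors"))
  expect_identical(n, 7L)
  # decoys only
  fr0 <- planted_hbond_frame(0, 3, 3, seed = 407)
  expect_identical(hydrogen_bonds(fr0, attr(fr0, "donors"),
                                  attr(fr0, "hydrogens"),
                                  attr(fr0, "acceptors")), 0L)
  # count is symmetric under storage-order reversal of the triples
  rev_idx <- rev(seq_along(attr(fr, "donors")))
  expect_identical(hydrogen_bonds(fr, attr(fr, "donors")[rev_idx],
                                  attr(fr, "hydrogens")[rev_idx],
                                  attr(fr, "acceptors")), 7L)
})

test_that("SASA: isolated sphere, occlusion, and the two-sphere closed form", {
  fr <- md_frame(matrix(c(2, 2, 2), 1, 3), 8, "sorbate", "carbon",
                 radius = 0.2)
  s <- sasa(fr, probe_radius = 0.14, n_sphere_points = 960)
  expect_equal(s$total, 4 * pi * 0.34^2, tolerance = 0.01)
  expect_equal(s$carbon_fraction, 1)

  # atom enclosed by a shell of larger spheres
  shell_dirs <- rbind(diag(3), -diag(3))
  coords <- rbind(c(4, 4, 4), sweep(0.25 * shell_dirs, 2, c(4, 4, 4), "+"))
  enc <- md_frame(coords, 10, "s", "carbon", radius = c(0.1, rep(0.4, 6)))
  s_enc <- sasa(enc, n_sphere_points = 960)
  expect_lt(s_enc$atom_area[1] / (4 * pi * 0.24^2), 0.02)

  # two equal spheres vs the analytic buried-cap area
  d <- 0.3; R <- 0.2 + 0.14
  fr2 <- md_frame(rbind(c(2, 2, 2), c(2 + d, 2, 2)), 8, "sorbate",
                  c("carbon", "heteroatom"), radius = 0.2)
  s2 <- sasa(fr2, n_sphere_points = 960)
  expect_equal(s2$total, two_sphere_sasa(R, d), tolerance = 0.02)
  expect_equal(s2$carbon_fraction + s2$heteroatom_fraction, 1)

  expect_error(sasa(md_frame(matrix(0, 1, 3) + 1, 5, "x", "carbon",
                             radius = 0)), "radius")
})

test_that("pair interaction energies: closed forms and symmetry", {
  # zero charges -> zero electrostatics
  c6 <- 1e-3; c12 <- 1e-6
  rmin <- (2 * c12 / c6)^(1 / 6)
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + rmin, 1, 1)), 10, "a", "carbon",
                 charge = 0, c6 = c6, c12 = c12)
  e <- pair_interaction_energy(fr, 1, 2)
  expect_equal(unname(e["electrostatic"]), 0)
  expect_equal(unname(e["vdw"]), -c6^2 / (4 * c12))

  # unit charges at 0.5 nm with reaction field: hand-evaluated expression
  fr2 <- md_frame(rbind(c(1, 1, 1), c(1.5, 1, 1)), 10, "a", "carbon",
                  charge = c(1, 1), c6 = 0, c12 = 0)
  e2 <- pair_interaction_energy(fr2, 1, 2, cutoff = 1.4, eps_rf = 61)
  crf <- (2 * 61 - 2) / (2 * 61 + 1)
  hand <- 138.935458 * (1 / 0.5 + crf * 0.5^2 / (2 * 1.4^3) -
                          (1 + crf / 2) / 1.4)
  expect_equal(unname(e2["electrostatic"]), hand)

  # symmetry and cutoff behaviour on a small random box
  set.seed(10)
  frr <- md_frame(matrix(runif(30, 0, 3), 10, 3), 3, rep(c("a", "b"), 5),
                  "carbon", charge = rnorm(10, 0, 0.3),
                  c6 = 1e-3, c12 = 1e-6)
  ga <- which(frr$species == "a"); gb <- which(frr$species == "b")
  expect_equal(pair_interaction_energy(frr, ga, gb),
               pair_interaction_energy(frr, gb, ga))
  # pairs beyond the cutoff contribute nothing
  far <- md_frame(rbind(c(0.5, 0.5, 0.5), c(2.0, 0.5, 0.5)), 3, "a",
                  "carbon", charge = 1, c6 = c6, c12 = c12)
  expect_equal(unname(pair_interaction_energy(far, 1, 2, cutoff = 1.4)),
               c(0, 0))
})
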