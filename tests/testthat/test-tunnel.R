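test_that("vdW assignment uses Bondi radii with a warned fallback", {
  expect_equal(assign_vdw(c("C", "O", "N", "S", "H")),
               c(1.70, 1.52, 1.55, 1.80, 1.20))
  expect_warning(r <- assign_vdw("X"), "fallback")
  expect_equal(r, 1.70)
})

test_that("a single carbon ring gives clearance radius 8.30", {
  ring <- make_pore_structure(data.frame(z = 0, radius = 10))
  prof <- profile_tunnel(ring, c(0, 0.4), z_step = 0.5)
  expect_equal(prof$radius[1], 8.30, tolerance = 0.05 / 8.3)
  expect_false(prof$capped[1])
  expect_equal(c(prof$cx[1], prof$cy[1]), c(0, 0), tolerance = 0.05)
})

test_that("pore generator validates its inputs", {
  expect_error(make_pore_structure(data.frame(z = c(0, 0), radius = 10)),
               "duplicated z")
  expect_error(make_pore_structure(data.frame(z = 0, radius = 1)),
               "vdW")
})

test_that("funnel profile is recovered within 0.2 A RMSE", {
  fun <- funnel_structure()
  truth <- attr(fun, "truth")
  prof <- profile_tunnel(fun, c(0, 20), z_step = 1)
  got <- prof$radius[match(truth$z, prof$z)]
  rmse <- sqrt(mean((got - truth$clearance)^2))
  expect_lt(rmse, 0.2)
  # per-slice truth is linear, so the fit should be too
  expect_gt(summary(lm(got ~ truth$z))$r.squared, 0.99)
})

test_that("slices without confining atoms are capped at r_max", {
  ring <- make_pore_structure(data.frame(z = 0, radius = 10))
  prof <- profile_tunnel(ring, c(40, 41), z_step = 1, r_max = 15)
  expect_true(all(prof$capped))
  expect_equal(prof$radius, rep(15, 2))
})

test_that("PDB writing and parsing round-trip the pore coordinates", {
  fun <- funnel_structure()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fun, f)
  back <- load_pdb(f)
  expect_equal(nrow(back$coords), nrow(fun$coords))
  expect_lt(max(abs(back$coords - fun$coords)), 1e-3)
  expect_equal(back$elements, fun$elements)
})

test_that("element inference falls back to the atom-name heuristic", {
  lines <- c(
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0, 1, 0),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- load_pdb(f)
  expect_equal(s$elements, "C")
  # water is filtered out by default
  lines2 <- c(lines[1],
              sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                      "HETATM", 2, "O", "HOH", "A", 2, 5.0, 5.0, 5.0, 1, 0),
              "END")
  writeLines(lines2, f)
  expect_equal(nrow(load_pdb(f)$coords), 1L)
  expect_equal(nrow(load_pdb(f, keep_solvent = TRUE)$coords), 2L)
})

test_that("reported radius never exceeds the true clearance at the centre", {
  fun <- funnel_structure()
  prof <- profile_tunnel(fun, c(2, 18), z_step = 2)
  for (i in seq_len(nrow(prof))) {
    true_cl <- msmflux:::.clearance(c(prof$cx[i], prof$cy[i], prof$z[i]),
                                    fun$coords, fun$vdw)
    expect_lte(prof$radius[i], true_cl + 1e-9)
  }
})

test_that("profile is invariant under translation and rotation about z", {
  ring <- make_pore_structure(data.frame(z = c(0, 2), radius = c(8, 8)))
  p0 <- profile_tunnel(ring, c(0, 2), z_step = 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- msmflux:::new_structure_atoms(
    ring$coords %*% R + matrix(c(3, -2, 5), nrow(ring$coords), 3,
                               byrow = TRUE),
    ring$elements)
  p1 <- profile_tunnel(moved, c(5, 7), z_step = 1, seed_point_xy = c(3, -2))
  expect_equal(p1$radius, p0$radius, tolerance = 1e-4)
  expect_equal(p1$cx, p0$cx + 3, tolerance = 1e-3)
})

test_that("inflating all vdW radii by delta shrinks clearances by delta", {
  fun <- funnel_structure()
  prof <- profile_tunnel(fun, c(5, 10), z_step = 2.5)
  delta <- 0.25
  for (i in seq_len(nrow(prof))) {
    c0 <- msmflux:::.clearance(c(prof$cx[i], prof$cy[i], prof$z[i]),
                               fun$coords, fun$vdw)
    c1 <- msmflux:::.clearance(c(prof$cx[i], prof$cy[i], prof$z[i]),
                               fun$coords, fun$vdw + delta)
    expect_equal(c0 - c1, delta, tolerance = 1e-12)
  }
})

test_that("sphere-per-slice PDB export writes one probe per defined slice", {
  fun <- funnel_structure()
  prof <- profile_tunnel(fun, c(0, 10), z_step = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_profile_pdb(prof, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^HETATM", txt)), nrow(prof))
})
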