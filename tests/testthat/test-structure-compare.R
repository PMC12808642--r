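test_that("superposition is exact on planted transforms and rejects reflections", {
  gen <- generateComplex(tinySpec())
  m <- gen$model

  ## model vs itself: identity
  tr <- superposeOnReference(m, m, "PsaA")
  expect_equal(tr@rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tr@rmsd, 0, tolerance = 1e-9)

  ## 5 degrees about z + (3, 0, 0): recovered to 1e-6
  moved <- perturbComplex(m, rotation_deg = 5, axis = c(0, 0, 1),
                          center = c(0, 0, 0), translation = c(3, 0, 0))
  tr5 <- superposeOnReference(m, moved, "PsaA")
  ## the recovered transform is the inverse motion
  R_true <- t(PigmentNet:::rotationMatrix(5, c(0, 0, 1)))
  expect_lt(max(abs(tr5@rotation - R_true)), 1e-6)
  expect_lt(tr5@rmsd, 1e-6)
  ## applying it to the moved reference atoms restores the originals
  a <- atoms(m); a <- a[a$chain_id == "A1", ]
  b <- atoms(moved); b <- b[b$chain_id == "A1", ]
  restored <- applyTransform(as.matrix(b[, c("x", "y", "z")]), tr5)
  expect_lt(max(abs(restored - as.matrix(a[, c("x", "y", "z")]))), 1e-6)

  ## random transforms up to 30 degrees / 20 A: recovery to 1e-6
  set.seed(5)
  for (i in 1:8) {
    ang <- runif(1, -30, 30); ax <- runitvec(); tv <- runif(3, -20, 20)
    mv <- perturbComplex(m, ang, ax, center = c(0, 0, 0), translation = tv)
    tri <- superposeOnReference(m, mv, "PsaA")
    expect_lt(tri@rmsd, 1e-6)
    Ri <- t(PigmentNet:::rotationMatrix(ang, ax))
    expect_lt(max(abs(tri@rotation - Ri)), 1e-6)
  }
  expect_equal(det(tr5@rotation), 1, tolerance = 1e-9)

  ## noisy copy: RMSD on the expected scale, transform near truth
  noisy <- perturbComplex(m, rotation_deg = 10, axis = c(0, 0, 1),
                          center = c(0, 0, 0), noise_sd = 0.2, seed = 9L)
  trn <- superposeOnReference(m, noisy, "PsaA")
  ## per-atom deviation ~ sqrt(2) * sigma in 3-D after fitting
  expect_gt(trn@rmsd, 0.1)
  expect_lt(trn@rmsd, 0.6)

  expect_error(superposeOnReference(m, m, "PsaX"), "not found")
})

test_that("Kabsch agrees with an independent Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  A <- matrix(rnorm(45, sd = 10), ncol = 3)
  R <- PigmentNet:::rotationMatrix(17, c(1, 2, 3))
  B <- sweep(A %*% t(R), 2, c(4, -2, 7), "+")   # A rotated+translated
  ## package route: map B back onto A
  sa <- data.frame(chain_id = "R", residue_name = "ALA",
                   residue_number = 1:15, atom_name = "CA",
                   x = A[, 1], y = A[, 2], z = A[, 3], element = "C")
  sb <- sa; sb[, c("x", "y", "z")] <- B
  subs <- data.frame(chain_id = "R", role = "PsaA", ring = "none",
                     ring_index = NA_integer_)
  ma <- ComplexModel("a", subs, atoms = sa)
  mb <- ComplexModel("b", subs, atoms = sb)
  tr <- superposeOnReference(ma, mb, "PsaA")
  ## vegan::procrustes solves the same rotation (it maps A-centered onto B)
  pv <- vegan::procrustes(A, B, scale = FALSE)
  expect_lt(max(abs(tr@rotation - t(pv$rotation))), 1e-8)
  expect_lt(tr@rmsd, 1e-9)
})

test_that("subunit shifts decompose displacements and satisfy Pythagoras", {
  gen <- generateComplex(tinySpec())
  fr <- membraneFrame(gen$model)
  m <- assignRings(gen$model, fr)

  ## identical models: all shifts zero
  tr0 <- superposeOnReference(m, m, "PsaA")
  sh0 <- subunitShifts(m, m, tr0, fr)
  expect_equal(max(sh0$total), 0, tolerance = 1e-9)

  ## one subunit translated 8 A in-plane; decomposition against the exact
  ## construction frame (the estimated normal carries ~0.1 degree of
  ## numerical tilt, which would leak a few hundredths into `vertical`)
  tf <- gen$truth@frame
  mv <- perturbComplex(m, translation = c(8, 0, 0), chains = "I02")
  sh <- subunitShifts(m, mv, superposeOnReference(m, mv, "PsaA"), tf)
  row <- sh[sh$chain_a == "I02", ]
  expect_equal(row$horizontal, 8, tolerance = 1e-6)
  expect_equal(row$vertical, 0, tolerance = 1e-6)
  others <- sh[sh$chain_a != "I02", ]
  expect_lt(max(others$total), 1e-6)

  ## one subunit moved 3 A along the normal toward the cytoplasmic marker
  mv2 <- perturbComplex(m, translation = 3 * tf@normal, chains = "O03")
  sh2 <- subunitShifts(m, mv2, superposeOnReference(m, mv2, "PsaA"), tf)
  expect_equal(sh2$vertical[sh2$chain_a == "O03"], 3, tolerance = 1e-6)

  ## Pythagorean invariant on a randomly perturbed copy
  set.seed(77)
  mv3 <- m
  for (ch in sample(subunits(m)$chain_id[subunits(m)$role == "isia"], 5))
    mv3 <- perturbComplex(mv3, translation = rnorm(3, sd = 4), chains = ch)
  sh3 <- subunitShifts(m, mv3, superposeOnReference(m, mv3, "PsaA"), fr)
  expect_equal(sh3$total^2, sh3$horizontal^2 + sh3$vertical^2,
               tolerance = 1e-6)
})

test_that("ring rotation angles are recovered with the stated sign convention", {
  gen <- generateComplex(tinySpec())
  fr <- membraneFrame(gen$model)
  m <- assignRings(gen$model, fr)

  tr0 <- superposeOnReference(m, m, "PsaA")
  expect_equal(as.numeric(ringRotationAngle(m, m, tr0, fr, "outer")), 0,
               tolerance = 1e-9)

  ## outer ring rotated by +5 degrees about the axis (anticlockwise viewed
  ## from the lumenal side = about -normal in the generator's +z frame)
  outer <- subunits(m)$chain_id[subunits(m)$ring == "outer"]
  mv <- perturbComplex(m, rotation_deg = 5, axis = -fr@normal,
                       center = c(0, 0, 0), chains = outer)
  trv <- superposeOnReference(m, mv, "PsaA")
  ## mapping the rotated ring back onto the reference: -5 degrees
  ang <- ringRotationAngle(m, mv, trv, fr, "outer")
  expect_equal(abs(as.numeric(ang)), 5, tolerance = 0.05)
  expect_equal(as.numeric(ang), -5, tolerance = 0.05)
  expect_equal(attr(ang, "per_subunit_mean"), -5, tolerance = 0.05)
  ## the inner ring did not move
  expect_equal(as.numeric(ringRotationAngle(m, mv, trv, fr, "inner")), 0,
               tolerance = 1e-6)

  ## too few matched subunits
  one <- subsetChains(m, c("A1", "K1", "C", "D", "E", "I01"))
  expect_error(
    suppressWarnings(ringRotationAngle(m, one,
                                       superposeOnReference(m, one, "PsaA"),
                                       fr, "outer")),
    "at least 2")
})

test_that("curvature profiles report peak-to-peak vertical modulation", {
  flat <- generateComplex(tinySpec())
  fr <- membraneFrame(flat$model)
  mf <- assignRings(flat$model, fr)
  cp <- curvatureProfile(mf, fr)
  expect_lt(max(cp$peak_to_peak), 0.5)

  ## a cos(theta) vertical modulation is largely indistinguishable from a
  ## rigid tilt, which the PCA normal absorbs; measure against the exact
  ## construction frame instead
  bent <- generateComplex(tinySpec(curvatureAmplitude = 10))
  tf <- bent$truth@frame
  mb <- assignRings(bent$model, tf)
  cb <- curvatureProfile(mb, tf)
  expect_equal(unname(cb$peak_to_peak["outer"]), 10, tolerance = 0.5)
  ## 4 protomers at 90-degree pitch sample cos(theta) at +/-1, 0:
  ## full amplitude visible on the inner ring too
  expect_equal(unname(cb$peak_to_peak["inner"]), 10, tolerance = 0.5)

  ## invariant under rigid motion of the whole model (frame co-rotated)
  R <- PigmentNet:::rotationMatrix(33, c(2, 1, 1))
  mvb <- perturbComplex(mb, rotation_deg = 33, axis = c(2, 1, 1),
                        translation = c(10, -4, 6))
  tf2 <- MembraneFrame(as.numeric(R %*% tf@normal))
  cb2 <- curvatureProfile(mvb, tf2)
  expect_equal(cb2$peak_to_peak, cb$peak_to_peak, tolerance = 1e-6)
})
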