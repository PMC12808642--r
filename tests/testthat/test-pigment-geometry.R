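test_that("membrane frame recovers the construction normal and is equivariant", {
  gen <- generateComplex(tinySpec())
  fr <- membraneFrame(gen$model)
  ang <- acos(abs(sum(fr@normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 0.5)
  ## sign fixed by the extrinsic marker: +z is cytoplasmic
  expect_gt(sum(fr@normal * c(0, 0, 1)), 0)
  expect_lt(abs(fr@midplaneOffset), 2)   # layers at +9/-9 -> midplane ~0

  ## rigid rotation of the whole model rotates the normal accordingly
  rot <- perturbComplex(gen$model, rotation_deg = 37, axis = c(1, 2, 0.5),
                        translation = c(5, -3, 11))
  fr2 <- membraneFrame(rot)
  R <- PigmentNet:::rotationMatrix(37, c(1, 2, 0.5))
  expected <- as.numeric(R %*% fr@normal)
  ang2 <- acos(pmin(1, abs(sum(fr2@normal * expected)))) * 180 / pi
  expect_lt(ang2, 0.5)

  ## degenerate input
  two <- chlModel(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_error(membraneFrame(two), "at least 3")
  ## no marker and no declared positive side
  expect_error(membraneFrame(chlModel(diag(3) * 10)), "marker")
  expect_s4_class(
    membraneFrame(chlModel(diag(3) * 10), positive_point = c(0, 0, 50)),
    "MembraneFrame")
})

test_that("sidedness classification reproduces the two-layer construction", {
  gen <- generateComplex()    # 43 protomers x (11 cyto + 6 lumenal)
  fr <- membraneFrame(gen$model)
  cls <- classifySidedness(gen$model, fr, roles = "isia")
  expect_identical(unname(cls$counts["cytoplasmic"]), 473L)
  expect_identical(unname(cls$counts["lumenal"]), 258L)
  expect_identical(sum(cls$counts), nrow(cls$labels))

  ## per-pigment labels match the generator's ground truth exactly
  truth <- gen$truth@sidedness
  got <- cls$labels$side[match(truth$pigment_id, cls$labels$pigment_id)]
  expect_identical(got, truth$side)

  ## invariance under rigid motion
  moved <- perturbComplex(gen$model, rotation_deg = 63, axis = c(1, 0, 1),
                          translation = c(-20, 14, 8))
  cls2 <- classifySidedness(moved, membraneFrame(moved), roles = "isia")
  expect_identical(cls$counts, cls2$counts)
  got2 <- cls2$labels$side[match(truth$pigment_id, cls2$labels$pigment_id)]
  expect_identical(got2, truth$side)

  ## all pigments strictly on one side
  one <- chlModel(cbind(runif(6, 0, 30), runif(6, 0, 30), runif(6, 4, 12)))
  fr1 <- MembraneFrame(c(0, 0, 1), midplaneOffset = 0)
  c1 <- classifySidedness(one, fr1)
  expect_identical(unname(c1$counts["lumenal"]), 0L)
})

test_that("ring assignment splits radii and indexes protomers like the truth", {
  gen <- generateComplex()
  fr <- membraneFrame(gen$model)
  m <- assignRings(gen$model, fr)
  s <- subunits(m)
  expect_identical(sum(s$ring == "inner"), 18L)
  expect_identical(sum(s$ring == "outer"), 25L)
  truth <- gen$truth@rings
  got <- s[match(truth$chain_id, s$chain_id), c("ring", "ring_index")]
  expect_identical(got$ring, truth$ring)
  expect_identical(got$ring_index, truth$ring_index)

  ## invariant under subunit list order and rigid motion
  shuf <- ComplexModel(modelName(gen$model),
                       subunits(gen$model)[rev(seq_len(nrow(subunits(gen$model)))), ],
                       pigments(gen$model), atoms(gen$model))
  moved <- perturbComplex(shuf, rotation_deg = 120, axis = c(0, 1, 3),
                          translation = c(7, 7, -7))
  m2 <- assignRings(moved, membraneFrame(moved))
  s2 <- subunits(m2)
  got2 <- s2[match(truth$chain_id, s2$chain_id), c("ring", "ring_index")]
  expect_identical(got2$ring, truth$ring)
  expect_identical(got2$ring_index, truth$ring_index)

  ## single-ring fixture: flagged, not an error
  single <- generateComplex(tinySpec(outerCount = 0L))
  fs <- membraneFrame(single$model)
  expect_message(ms <- assignRings(single$model, fs), "single|one radial")
  ss <- subunits(ms)
  expect_true(all(ss$ring[ss$role == "isia"] == "inner"))

  ## explicit override wins
  ov <- assignRings(gen$model, fr,
                    rings = list(inner = sprintf("O%02d", 1:25),
                                 outer = sprintf("I%02d", 1:18)))
  so <- subunits(ov)
  expect_identical(sum(so$ring == "inner"), 25L)
})

test_that("interfacial pairs respect boundary semantics and match brute force", {
  thr <- GeometryThresholds()
  ## 22.9 A apart in different subunits: in; 23.1 A: out
  near <- chlModel(rbind(c(0, 0, 0), c(22.9, 0, 0)))
  far <- chlModel(rbind(c(0, 0, 0), c(23.1, 0, 0)))
  expect_identical(nrow(interfacialPairs(near, thr)), 1L)
  expect_identical(nrow(interfacialPairs(far, thr)), 0L)
  ## exactly at the cutoff: inclusive
  at <- chlModel(rbind(c(0, 0, 0), c(23, 0, 0)))
  expect_identical(nrow(interfacialPairs(at, thr)), 1L)
  ## highlight is strict: 18.0 is not "under 18"
  h <- interfacialPairs(chlModel(rbind(c(0, 0, 0), c(18, 0, 0))), thr)
  expect_false(h$highlight[1])
  h2 <- interfacialPairs(chlModel(rbind(c(0, 0, 0), c(17.9, 0, 0))), thr)
  expect_true(h2$highlight[1])

  ## same-subunit pairs are never interfacial
  same <- chlModel(rbind(c(0, 0, 0), c(10, 0, 0)), chains = c("A", "A"))
  expect_identical(nrow(interfacialPairs(same, thr)), 0L)

  ## property: equality with the O(N^2) oracle on random fixtures
  for (seed in 1:5) {
    m <- randomChlModel(60, n_chains = 6, seed = seed)
    got <- interfacialPairs(m, thr)
    want <- oraclePairs(m, thr@pairCutoff)
    expect_setequal(pairKey(got$pigment_a, got$pigment_b),
                    pairKey(want$a, want$b))
    ## distances sorted ascending
    expect_true(!is.unsorted(got$mg_mg_distance))
  }

  ## category labelling on the generated double ring
  gen <- generateComplex(tinySpec())
  m <- assignRings(gen$model, membraneFrame(gen$model))
  pp <- interfacialPairs(m)
  io <- pp[pp$category == "inner_outer", ]
  s <- subunits(m)
  ringOf <- function(ch) s$ring[match(ch, s$chain_id)]
  expect_true(all(ringOf(io$chain_a) != ringOf(io$chain_b)))
  only_io <- interfacialPairs(m, categories = "inner_outer")
  expect_identical(sort(pairKey(only_io$pigment_a, only_io$pigment_b)),
                   sort(pairKey(io$pigment_a, io$pigment_b)))
})
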