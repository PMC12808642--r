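test_that("transition dipoles follow the NB->ND axis and reject degeneracy", {
  m <- chlModel(c(5, 5, 5), u = c(1, 0, 0))
  d <- transitionDipoles(m)
  expect_equal(unlist(d[1, c("ux", "uy", "uz")]), c(ux = 1, uy = 0, uz = 0))

  ## nb == nd is a degenerate dipole and must name the pigment
  p <- pigments(m)
  p[, c("nd_x", "nd_y", "nd_z")] <- p[, c("nb_x", "nb_y", "nb_z")]
  expect_error(transitionDipoles(p), p$pigment_id[1])

  ## flipping NB/ND leaves kappa^2 unchanged for random pairs
  set.seed(42)
  for (i in 1:25) {
    ud <- runitvec(); ua <- runitvec(); rv <- rnorm(3) * 10
    k1 <- kappaSquared(ud, ua, rv)
    expect_equal(kappaSquared(-ud, ua, rv), k1, tolerance = 1e-12)
    expect_equal(kappaSquared(ud, -ua, rv), k1, tolerance = 1e-12)
    ## donor/acceptor exchange symmetry
    expect_equal(kappaSquared(ua, ud, -rv), k1, tolerance = 1e-12)
  }
})

test_that("kappa^2 analytic cases are exact and the range is [0, 4]", {
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  expect_identical(kappaSquared(z, z, z), 4)       # collinear head-to-tail
  expect_identical(kappaSquared(x, y, z), 0)       # mutually orthogonal
  expect_identical(kappaSquared(x, x, z), 1)       # parallel, perpendicular to R
  expect_error(kappaSquared(x, x, c(0, 0, 0)), "zero-length")

  set.seed(7)
  n <- 2e4
  ud <- matrix(rnorm(3 * n), ncol = 3); ud <- ud / sqrt(rowSums(ud^2))
  ua <- matrix(rnorm(3 * n), ncol = 3); ua <- ua / sqrt(rowSums(ua^2))
  rv <- matrix(rnorm(3 * n), ncol = 3)
  k <- kappaSquared(ud, ua, rv)
  expect_true(all(k >= 0 & k <= 4 + 1e-12))
  ## isotropic average 2/3 within 3 standard errors
  expect_lt(abs(mean(k) - 2 / 3), 3 * sd(k) / sqrt(n))
})

test_that("the pairwise rate matches the closed form and its scaling laws", {
  ## kappa^2 = 1, R = 2.0 nm: parallel dipoles perpendicular to the axis
  m <- chlModel(rbind(c(0, 0, 0), c(0, 0, 20)),
                u = rbind(c(1, 0, 0), c(1, 0, 0)))
  p <- pigments(m)
  e <- fretRate(p[1, ], p[2, ])
  expected_rate <- 32.26 / (1.55^4 * 2^6)   # independent hand evaluation
  expect_equal(e$kappa_sq, 1, tolerance = 1e-12)
  expect_equal(e$rate, expected_rate, tolerance = 1e-12)
  expect_equal(e$rate, 0.08733, tolerance = 1e-4)
  expect_equal(e$lifetime, 11.45, tolerance = 1e-3)

  ## kappa^2 = 0: zero rate, no finite lifetime
  m0 <- chlModel(rbind(c(0, 0, 0), c(0, 0, 20)),
                 u = rbind(c(1, 0, 0), c(0, 1, 0)))
  p0 <- pigments(m0)
  e0 <- fretRate(p0[1, ], p0[2, ])
  expect_identical(e0$rate, 0)
  expect_identical(e0$lifetime, Inf)

  ## doubling R at fixed kappa^2 divides the rate by exactly 64
  m2 <- chlModel(rbind(c(0, 0, 0), c(0, 0, 40)),
                 u = rbind(c(1, 0, 0), c(1, 0, 0)))
  e2 <- fretRate(pigments(m2)[1, ], pigments(m2)[2, ])
  expect_equal(e$rate / e2$rate, 64, tolerance = 1e-10)

  ## symmetric under donor/acceptor exchange
  expect_equal(fretRate(p[2, ], p[1, ])$rate, e$rate, tolerance = 1e-12)

  expect_error(fretRate(p[1, ], p[1, ]), "coincident")

  ## rate strictly decreasing in R, linear in kappa^2 (via C linearity)
  rates <- vapply(seq(10, 30, by = 5), function(R) {
    mm <- chlModel(rbind(c(0, 0, 0), c(0, 0, R)),
                   u = rbind(c(1, 0, 0), c(1, 0, 0)))
    fretRate(pigments(mm)[1, ], pigments(mm)[2, ])$rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("the network equals the brute-force oracle on random fixtures", {
  for (seed in 1:6) {
    n <- c(20, 40, 60, 80, 50, 30)[seed]
    m <- randomChlModel(n, n_chains = 5, seed = seed)
    g <- buildNetwork(m)
    want <- oracleEdges(m)
    expect_equal(igraph::ecount(g), nrow(want))
    if (!nrow(want)) next
    ends <- igraph::ends(g, igraph::E(g))
    got_key <- pairKey(ends[, 1], ends[, 2])
    expect_setequal(got_key, want$key)
    ord <- match(want$key, got_key)
    expect_equal(igraph::edge_attr(g, "rate")[ord], want$rate,
                 tolerance = 1e-10)
    expect_equal(igraph::edge_attr(g, "kappa_sq")[ord], want$kappa_sq,
                 tolerance = 1e-10)
  }

  ## empty pigment list -> empty graph
  g0 <- buildNetwork(ComplexModel("none"))
  expect_equal(igraph::vcount(g0), 0L)
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("lifetime filtering and edge categories behave as documented", {
  gen <- generateComplex(tinySpec())
  fr <- membraneFrame(gen$model)
  m <- assignRings(gen$model, fr)
  g <- buildNetwork(m, frame = fr)
  lt <- igraph::edge_attr(g, "lifetime")
  g40 <- filterByLifetime(g, 40)
  expect_equal(igraph::ecount(g40), sum(lt < 40))
  expect_true(all(igraph::edge_attr(g40, "lifetime") < 40))
  ## categories are consistent with subunit metadata
  s <- subunits(m)
  ends <- igraph::ends(g, igraph::E(g))
  chainOf <- function(id) sub(":.*", "", id)
  cat <- igraph::edge_attr(g, "category")
  same <- chainOf(ends[, 1]) == chainOf(ends[, 2])
  expect_true(all(cat[same] == "intra_subunit"))
  expect_true(all(cat[!same] != "intra_subunit"))
  ringOf <- function(ch) s$ring[match(ch, s$chain_id)]
  io <- cat == "inner_outer"
  expect_true(all(ringOf(chainOf(ends[io, 1])) != ringOf(chainOf(ends[io, 2]))))
})

test_that("the outer-to-inner table ranks planted pairs by rate", {
  ## three planted inter-ring pairs with distinct rates (distance-graded)
  mg <- rbind(c(0, 0, 0), c(14, 0, 0),
              c(100, 0, 0), c(100, 16, 0),
              c(200, 0, 0), c(200, 0, 19))
  u <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1),
             c(0, 1, 0), c(0, 1, 0))
  chains <- c("I01", "O01", "I02", "O02", "I03", "O03")
  m <- chlModel(mg, u, chains)
  s <- subunits(m)
  s$ring <- ifelse(startsWith(s$chain_id, "I"), "inner", "outer")
  s$ring_index <- as.integer(sub("^.", "", s$chain_id))
  m <- ComplexModel("planted", s, pigments(m))
  g <- buildNetwork(m)
  tab <- outerToInnerTable(g)
  expect_identical(nrow(tab$edges), 3L)
  ## fastest first; distances 14 < 16 < 19 with same-kappa geometry
  expect_identical(tab$edges$donor_subunit, c("O01", "O02", "O03"))
  expect_true(all(tab$edges$donor_subunit ==
                    c("O01", "O02", "O03")))
  expect_true(!is.unsorted(-tab$edges$rate))
  ## donors are on the outer ring by orientation convention
  expect_true(all(startsWith(tab$edges$donor, "O")))
  ## per-subunit summary has one row per pair here
  expect_identical(nrow(tab$subunit_summary), 3L)

  ## no inner/outer edges -> empty table
  g0 <- buildNetwork(chlModel(rbind(c(0, 0, 0), c(12, 0, 0))))
  t0 <- outerToInnerTable(g0)
  expect_identical(nrow(t0$edges), 0L)
})

test_that("graph export round-trips in graphml, gexf and tsv", {
  m <- chlModel(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 13, 0)))
  g <- buildNetwork(m)
  expect_gt(igraph::ecount(g), 0)
  for (fmt in c("graphml", "gexf", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportGraph(g, f, fmt)
    g2 <- importGraph(f, fmt)
    expect_setequal(igraph::vertex_attr(g2, "name")[igraph::degree(g2) > 0],
                    igraph::vertex_attr(g, "name")[igraph::degree(g) > 0])
    e1 <- igraph::ends(g, igraph::E(g)); e2 <- igraph::ends(g2, igraph::E(g2))
    expect_setequal(pairKey(e2[, 1], e2[, 2]), pairKey(e1[, 1], e1[, 2]))
    w1 <- igraph::edge_attr(g, "weight")[match(pairKey(e2[, 1], e2[, 2]),
                                               pairKey(e1[, 1], e1[, 2]))]
    expect_equal(igraph::edge_attr(g2, "weight"), w1, tolerance = 1e-9)
    expect_true(all(igraph::edge_attr(g2, "weight") > 0))
  }
  ## empty graph: valid document in every format
  g0 <- buildNetwork(ComplexModel("none"))
  for (fmt in c("graphml", "gexf", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportGraph(g0, f, fmt)
    expect_equal(igraph::ecount(importGraph(f, fmt)), 0L)
  }
})
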