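## Parametric pseudo-complex generator with full ground truth. The generator
## stands in for deposited cryo-EM models: concentric antenna rings around a
## core, each protomer carrying a fixed chlorophyll complement with Mg/NB/ND
## pseudo-atoms in two membrane layers, so sidedness labels, ring
## assignments, interfacial pairs and transfer networks are known by
## construction.

CHL_RESNAME <- "CLA"
CAR_RESNAME <- "BCR"

## evaluate expr with a local RNG state seeded from `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' SyntheticComplexSpec: parameterization of a generated pseudo-complex
#'
#' Defaults encode the trimeric double-ring supercomplex: 18 inner + 25 outer
#' antenna protomers, 17 chlorophylls a (11 cytoplasmic + 6 lumenal) and 4
#' carotenoids per protomer, rings at 110/155 Angstrom radius, chlorophyll
#' layers at +9/-9 Angstrom along the membrane normal (+z, cytoplasmic).
#'
#' @slot innerCount,outerCount protomers per ring.
#' @slot chlPerSubunit,carotenoidsPerSubunit cofactors per protomer.
#' @slot innerRadius,outerRadius ring radii, Angstrom.
#' @slot layerOffsets named numeric, cytoplasmic/lumenal layer heights.
#' @slot layerAllocation named integer, chlorophylls per layer
#'   (sums to chlPerSubunit).
#' @slot innerPitchDeg,outerPitchDeg angular pitch between protomers (degrees);
#'   360/count gives a closed ring, a fixed pitch with fewer protomers gives an
#'   open arc (the monomer's double layer).
#' @slot dipoleRule \code{"tangent"}, \code{"radial"} or \code{"random"}.
#' @slot coordinateNoiseSd Gaussian noise per coordinate, Angstrom.
#' @slot curvatureAmplitude peak-to-peak vertical modulation of protomer
#'   placement across the ring, Angstrom.
#' @slot coreCount number of core copies (3 = trimer, 1 = monomer).
#' @slot coreChlsPerCore chlorophylls per core copy.
#' @slot marker place cytoplasmic extrinsic marker subunits (PsaC/PsaD/PsaE).
#' @slot seed integer RNG seed (noise and random dipoles only).
#' @export
setClass("SyntheticComplexSpec",
  representation(innerCount = "integer", outerCount = "integer",
                 chlPerSubunit = "integer", carotenoidsPerSubunit = "integer",
                 innerRadius = "numeric", outerRadius = "numeric",
                 layerOffsets = "numeric", layerAllocation = "integer",
                 innerPitchDeg = "numeric", outerPitchDeg = "numeric",
                 dipoleRule = "character", coordinateNoiseSd = "numeric",
                 curvatureAmplitude = "numeric", coreCount = "integer",
                 coreChlsPerCore = "integer", marker = "logical",
                 seed = "integer"),
  prototype(innerCount = 18L, outerCount = 25L, chlPerSubunit = 17L,
            carotenoidsPerSubunit = 4L, innerRadius = 110, outerRadius = 155,
            layerOffsets = c(cytoplasmic = 9, lumenal = -9),
            layerAllocation = c(cytoplasmic = 11L, lumenal = 6L),
            innerPitchDeg = 20, outerPitchDeg = 14.4,
            dipoleRule = "tangent", coordinateNoiseSd = 0,
            curvatureAmplitude = 0, coreCount = 3L, coreChlsPerCore = 96L,
            marker = TRUE, seed = 1L))

setValidity("SyntheticComplexSpec", function(object) {
  msg <- character()
  if (object@innerCount < 0L || object@outerCount < 0L)
    msg <- c(msg, "ring counts must be >= 0")
  if (object@chlPerSubunit < 0L || object@carotenoidsPerSubunit < 0L)
    msg <- c(msg, "per-protomer cofactor counts must be >= 0")
  if (!(object@innerRadius < object@outerRadius))
    msg <- c(msg, "innerRadius must be < outerRadius")
  if (!identical(sort(names(object@layerOffsets)),
                 c("cytoplasmic", "lumenal")) ||
      object@layerOffsets["cytoplasmic"] <= object@layerOffsets["lumenal"])
    msg <- c(msg, "layerOffsets must be named cytoplasmic/lumenal with cytoplasmic above lumenal")
  if (!identical(sort(names(object@layerAllocation)),
                 c("cytoplasmic", "lumenal")) ||
      sum(object@layerAllocation) != object@chlPerSubunit)
    msg <- c(msg, "layerAllocation must be named and sum to chlPerSubunit")
  if (any(object@layerAllocation < 0L))
    msg <- c(msg, "layerAllocation entries must be >= 0")
  if (object@innerPitchDeg <= 0 || object@outerPitchDeg <= 0)
    msg <- c(msg, "angular pitches must be positive")
  if (object@innerPitchDeg * object@innerCount > 360 + 1e-9 ||
      object@outerPitchDeg * object@outerCount > 360 + 1e-9)
    msg <- c(msg, "pitch x count must not exceed 360 degrees")
  if (!object@dipoleRule %in% c("tangent", "radial", "random"))
    msg <- c(msg, "dipoleRule must be tangent, radial or random")
  if (object@coordinateNoiseSd < 0)
    msg <- c(msg, "coordinateNoiseSd must be >= 0")
  if (object@coreCount < 0L) msg <- c(msg, "coreCount must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticComplexSpec", function(object) {
  cat("SyntheticComplexSpec:", object@innerCount, "inner +",
      object@outerCount, "outer protomers x", object@chlPerSubunit,
      "Chl a; radii", object@innerRadius, "/", object@outerRadius,
      "A; noise sd", object@coordinateNoiseSd, "A; seed", object@seed, "\n")
  invisible(object)
})

#' Construct a synthetic complex specification
#'
#' @param preset \code{"trimer"} (closed 18+25 double ring, 3 cores) or
#'   \code{"monomer"} (open 6+7 double layer, 1 core, same angular pitches as
#'   the trimer).
#' @param ... slot overrides (see \code{\linkS4class{SyntheticComplexSpec}}).
#' @return a validated \code{SyntheticComplexSpec}.
#' @export
syntheticComplexSpec <- function(preset = c("trimer", "monomer"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "monomer") {
    defaults <- list(innerCount = 6L, outerCount = 7L, coreCount = 1L)
    for (nm in names(defaults))
      if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  ints <- c("innerCount", "outerCount", "chlPerSubunit",
            "carotenoidsPerSubunit", "coreCount", "coreChlsPerCore", "seed")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  if (!is.null(args$layerAllocation))
    args$layerAllocation <- vapply(args$layerAllocation, as.integer, 1L)
  do.call(new, c(list("SyntheticComplexSpec"), args))
}

#' GroundTruth: the known answers for a generated complex
#'
#' @slot spec the generating \code{SyntheticComplexSpec}.
#' @slot chainRoles named character vector (chain id to role), the naming
#'   configuration a parser needs to recover roles after a file round trip.
#' @slot sidedness data.frame \code{pigment_id}, \code{side} for every
#'   chlorophyll.
#' @slot rings data.frame \code{chain_id}, \code{ring}, \code{ring_index} for
#'   every antenna protomer.
#' @slot frame the true \code{MembraneFrame}.
#' @slot pairs data.frame of all different-subunit chlorophyll pairs within
#'   23 Angstrom (brute force over the emitted coordinates).
#' @slot plantedPairs the five fastest inner/outer interface pairs by Forster
#'   rate, fastest first.
#' @export
setClass("GroundTruth",
  representation(spec = "SyntheticComplexSpec", chainRoles = "character",
                 sidedness = "data.frame", rings = "data.frame",
                 frame = "MembraneFrame", pairs = "data.frame",
                 plantedPairs = "data.frame"))

## canonical within-protomer chlorophyll layout for the 11 + 6 complement.
## local_angle is measured from the outward radial direction, in-plane;
## the interface chlorophylls sit on the outward (506/516/517) and inward
## (504/508/510/519) faces so that the named donor/acceptor pairs arise at
## the ring-ring interface by construction.
canonicalChlLayout <- function() {
  data.frame(
    number = c(501L, 502L, 503L, 508L, 509L, 511L, 512L, 513L, 516L, 517L,
               519L, 504L, 505L, 506L, 507L, 510L, 518L),
    layer = c(rep("cytoplasmic", 11), rep("lumenal", 6)),
    local_angle = c(0.9, 1.5, 2.1, pi, 4.2, 4.8, 5.4, 5.9, 0.0, 0.3,
                    pi + 0.6, pi - 0.3, 1.2, -0.3, 2.4, pi + 0.3, 4.5),
    local_radius = c(9, 9, 9, 14, 9, 9, 9, 9, 14, 14,
                     14, 14, 9, 14, 9, 14, 9),
    stringsAsFactors = FALSE)
}

chlLayoutFor <- function(alloc) {
  canon <- canonicalChlLayout()
  if (identical(unname(alloc[c("cytoplasmic", "lumenal")]), c(11L, 6L)))
    return(canon)
  build <- function(n, layer, start) {
    if (!n) return(canon[0, ])
    data.frame(number = as.integer(seq(start, length.out = n)), layer = layer,
               local_angle = seq(0, 2 * pi, length.out = n + 1)[seq_len(n)],
               local_radius = 11, stringsAsFactors = FALSE)
  }
  rbind(build(alloc[["cytoplasmic"]], "cytoplasmic", 501L),
        build(alloc[["lumenal"]], "lumenal",
              501L + alloc[["cytoplasmic"]]))
}

## helix-like C-alpha pseudo-trace around a center
caTrace <- function(center, n = 20L, radius = 15, zspan = 20) {
  t <- seq(0, 4 * pi, length.out = n)
  cbind(center[1] + radius * cos(t), center[2] + radius * sin(t),
        center[3] + seq(-zspan / 2, zspan / 2, length.out = n))
}

#' Generate a synthetic pseudo-complex with ground truth
#'
#' Protomers are placed at fixed angular pitch on each ring (anticlockwise as
#' viewed from the lumenal side, the ring-index convention); each carries its
#' chlorophyll complement in two layers with NB/ND pseudo-atoms 2.1 Angstrom
#' either side of Mg along the dipole direction, plus carotenoid centroids.
#' Core copies contribute C-alpha traces (PsaA, PsaK) and optionally
#' chlorophylls; extrinsic marker subunits (PsaC/PsaD/PsaE) sit on the
#' cytoplasmic side. Deterministic given the seed.
#'
#' @param spec a \code{\link{syntheticComplexSpec}}.
#' @param name model name.
#' @return list with \code{model} (a \code{ComplexModel}) and \code{truth}
#'   (a \code{\linkS4class{GroundTruth}}).
#' @export
generateComplex <- function(spec = syntheticComplexSpec(), name = "synthetic") {
  validObject(spec)
  layout <- chlLayoutFor(spec@layerAllocation)
  layout <- layout[seq_len(spec@chlPerSubunit), , drop = FALSE]
  zlayer <- spec@layerOffsets[layout$layer]
  ncar <- spec@carotenoidsPerSubunit
  car_start <- max(520L, if (nrow(layout)) max(layout$number) else 500L) + 1L

  subs <- list(); pigs <- list(); ats <- list()
  truth_rings <- list()

  addProtomer <- function(chain, ring, index, radius, theta, dz) {
    ur <- c(cos(theta), -sin(theta), 0)     # outward radial (lumenal-view)
    ut <- c(-sin(theta), -cos(theta), 0)    # tangent, direction of increasing theta
    center <- radius * ur + c(0, 0, dz)
    ## chlorophylls
    mg <- sweep(outer(layout$local_radius * cos(layout$local_angle), ur) +
                outer(layout$local_radius * sin(layout$local_angle), ut),
                2, center, "+")
    mg[, 3] <- mg[, 3] + zlayer
    u <- switch(spec@dipoleRule,
      tangent = matrix(ut, nrow(layout), 3, byrow = TRUE),
      radial = matrix(ur, nrow(layout), 3, byrow = TRUE),
      random = {
        v <- matrix(stats::rnorm(3 * nrow(layout)), ncol = 3)
        v / rowNorms(v)
      })
    nb <- mg - 2.1 * u
    nd <- mg + 2.1 * u
    pig <- data.frame(
      pigment_id = paste(chain, layout$number, CHL_RESNAME, sep = ":"),
      chain_id = chain, residue_number = layout$number,
      residue_name = CHL_RESNAME, pigment_class = "chlorophyll_a",
      x = mg[, 1], y = mg[, 2], z = mg[, 3],
      nb_x = nb[, 1], nb_y = nb[, 2], nb_z = nb[, 3],
      nd_x = nd[, 1], nd_y = nd[, 2], nd_z = nd[, 3],
      stringsAsFactors = FALSE)
    if (ncar > 0) {
      ca_ang <- seq(0.4, 2 * pi, length.out = ncar + 1)[seq_len(ncar)]
      cpos <- sweep(outer(6 * cos(ca_ang), ur) + outer(6 * sin(ca_ang), ut),
                    2, center, "+")
      car_num <- as.integer(seq(car_start, length.out = ncar))
      pig <- rbind(pig, data.frame(
        pigment_id = paste(chain, car_num, CAR_RESNAME, sep = ":"),
        chain_id = chain, residue_number = car_num,
        residue_name = CAR_RESNAME, pigment_class = "carotenoid",
        x = cpos[, 1], y = cpos[, 2], z = cpos[, 3],
        nb_x = NA_real_, nb_y = NA_real_, nb_z = NA_real_,
        nd_x = NA_real_, nd_y = NA_real_, nd_z = NA_real_,
        stringsAsFactors = FALSE))
    }
    tr <- caTrace(center)
    at <- data.frame(chain_id = chain, residue_name = "ALA",
                     residue_number = seq_len(nrow(tr)), atom_name = "CA",
                     x = tr[, 1], y = tr[, 2], z = tr[, 3], element = "C",
                     stringsAsFactors = FALSE)
    subs[[length(subs) + 1]] <<- data.frame(
      chain_id = chain, role = "isia", ring = ring,
      ring_index = as.integer(index), stringsAsFactors = FALSE)
    pigs[[length(pigs) + 1]] <<- pig
    ats[[length(ats) + 1]] <<- at
    truth_rings[[length(truth_rings) + 1]] <<- data.frame(
      chain_id = chain, ring = ring, ring_index = as.integer(index),
      stringsAsFactors = FALSE)
  }

  curv <- function(theta)
    if (spec@curvatureAmplitude > 0) spec@curvatureAmplitude / 2 * cos(theta)
    else 0
  for (k in seq_len(spec@innerCount)) {
    th <- (k - 1) * spec@innerPitchDeg * pi / 180
    addProtomer(sprintf("I%02d", k), "inner", k, spec@innerRadius, th, curv(th))
  }
  for (k in seq_len(spec@outerCount)) {
    th <- (k - 1) * spec@outerPitchDeg * pi / 180
    addProtomer(sprintf("O%02d", k), "outer", k, spec@outerRadius, th, curv(th))
  }

  ## core copies: PsaA trace + PsaK pole marker + optional core chlorophylls
  roles <- c()
  core_radius <- 62
  for (c_i in seq_len(spec@coreCount)) {
    th <- (c_i - 1) * 2 * pi / max(1L, spec@coreCount)
    ur <- c(cos(th), -sin(th), 0); ut <- c(-sin(th), -cos(th), 0)
    ccen <- core_radius * ur
    chA <- sprintf("A%d", c_i)
    tr <- caTrace(ccen, n = 30L, radius = 20, zspan = 24)
    ats[[length(ats) + 1]] <- data.frame(
      chain_id = chA, residue_name = "ALA",
      residue_number = seq_len(nrow(tr)), atom_name = "CA",
      x = tr[, 1], y = tr[, 2], z = tr[, 3], element = "C",
      stringsAsFactors = FALSE)
    subs[[length(subs) + 1]] <- data.frame(
      chain_id = chA, role = "PsaA", ring = "none",
      ring_index = NA_integer_, stringsAsFactors = FALSE)
    chK <- sprintf("K%d", c_i)
    ktr <- caTrace(85 * ur, n = 8L, radius = 5, zspan = 10)
    ats[[length(ats) + 1]] <- data.frame(
      chain_id = chK, residue_name = "ALA",
      residue_number = seq_len(nrow(ktr)), atom_name = "CA",
      x = ktr[, 1], y = ktr[, 2], z = ktr[, 3], element = "C",
      stringsAsFactors = FALSE)
    subs[[length(subs) + 1]] <- data.frame(
      chain_id = chK, role = "PsaK", ring = "none",
      ring_index = NA_integer_, stringsAsFactors = FALSE)
    roles[chA] <- "PsaA"; roles[chK] <- "PsaK"
    if (spec@coreChlsPerCore > 0) {
      n_cyt <- ceiling(spec@coreChlsPerCore / 2)
      n_lum <- spec@coreChlsPerCore - n_cyt
      mk <- function(n, z, start) {
        if (!n) return(NULL)
        a <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
        mg <- sweep(outer(22 * cos(a), ur) + outer(22 * sin(a), ut),
                    2, ccen, "+")
        mg[, 3] <- mg[, 3] + z
        ## local tangent of the core circle at each chlorophyll
        u <- outer(-sin(a), ur) + outer(cos(a), ut)
        u <- u / rowNorms(u)
        num <- as.integer(seq(start, length.out = n))
        data.frame(
          pigment_id = paste(chA, num, CHL_RESNAME, sep = ":"),
          chain_id = chA, residue_number = num, residue_name = CHL_RESNAME,
          pigment_class = "chlorophyll_a",
          x = mg[, 1], y = mg[, 2], z = mg[, 3],
          nb_x = mg[, 1] - 2.1 * u[, 1], nb_y = mg[, 2] - 2.1 * u[, 2],
          nb_z = mg[, 3] - 2.1 * u[, 3],
          nd_x = mg[, 1] + 2.1 * u[, 1], nd_y = mg[, 2] + 2.1 * u[, 2],
          nd_z = mg[, 3] + 2.1 * u[, 3], stringsAsFactors = FALSE)
      }
      pigs[[length(pigs) + 1]] <- rbind(
        mk(n_cyt, spec@layerOffsets["cytoplasmic"], 1101L),
        mk(n_lum, spec@layerOffsets["lumenal"], 1101L + n_cyt))
    }
  }
  if (spec@marker) {
    for (i in seq_along(c("C", "D", "E"))) {
      ch <- c("C", "D", "E")[i]
      mtr <- caTrace(c(core_radius, 0, 26) + c(0, 4 * (i - 2), 0), n = 6L,
                     radius = 4, zspan = 6)
      ats[[length(ats) + 1]] <- data.frame(
        chain_id = ch, residue_name = "ALA",
        residue_number = seq_len(nrow(mtr)), atom_name = "CA",
        x = mtr[, 1], y = mtr[, 2], z = mtr[, 3], element = "C",
        stringsAsFactors = FALSE)
      subs[[length(subs) + 1]] <- data.frame(
        chain_id = ch, role = c("PsaC", "PsaD", "PsaE")[i], ring = "none",
        ring_index = NA_integer_, stringsAsFactors = FALSE)
      roles[ch] <- c("PsaC", "PsaD", "PsaE")[i]
    }
  }

  subs <- do.call(rbind, subs)
  pigs <- if (length(pigs)) do.call(rbind, pigs) else emptyPigments()
  ats <- do.call(rbind, ats)
  for (ch in subs$chain_id[subs$role == "isia"]) roles[ch] <- "isia"

  if (spec@coordinateNoiseSd > 0 || spec@dipoleRule == "random") {
    noisy <- withSeed(spec@seed, {
      if (spec@coordinateNoiseSd > 0) {
        sd <- spec@coordinateNoiseSd
        for (cols in list(c("x", "y", "z"))) {
          ats[, cols] <- ats[, cols] +
            matrix(stats::rnorm(3 * nrow(ats), sd = sd), ncol = 3)
        }
        for (cols in list(c("x", "y", "z"), c("nb_x", "nb_y", "nb_z"),
                          c("nd_x", "nd_y", "nd_z"))) {
          m <- as.matrix(pigs[, cols])
          ok <- stats::complete.cases(m)
          m[ok, ] <- m[ok, ] + matrix(stats::rnorm(3 * sum(ok), sd = sd),
                                      ncol = 3)
          pigs[, cols] <- m
        }
      }
      list(ats = ats, pigs = pigs)
    })
    ats <- noisy$ats; pigs <- noisy$pigs
  }

  model <- ComplexModel(name, subs, pigs, ats)
  truth_rings <- do.call(rbind, truth_rings)
  frame <- MembraneFrame(c(0, 0, 1),
                         midplaneOffset = mean(spec@layerOffsets))
  chl <- pigs[pigs$pigment_class == "chlorophyll_a", , drop = FALSE]
  isia_chl <- chl[chl$chain_id %in% truth_rings$chain_id, , drop = FALSE]
  side_truth <- data.frame(
    pigment_id = isia_chl$pigment_id,
    side = ifelse(isia_chl$residue_number %in%
                    layout$number[layout$layer == "cytoplasmic"],
                  "cytoplasmic", "lumenal"),
    stringsAsFactors = FALSE)
  truth <- new("GroundTruth", spec = spec, chainRoles = roles,
               sidedness = side_truth, rings = truth_rings, frame = frame,
               pairs = bruteForcePairTruth(model, 23),
               plantedPairs = plantedPairTruth(model, truth_rings))
  list(model = model, truth = truth)
}

## brute-force different-subunit chlorophyll pairs within `cutoff` (loops on
## purpose: ground truth must not depend on the analysis implementation)
bruteForcePairTruth <- function(model, cutoff) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  out <- list()
  n <- nrow(chl)
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (chl$chain_id[i] == chl$chain_id[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff)
        out[[length(out) + 1]] <- data.frame(
          pigment_a = chl$pigment_id[i], pigment_b = chl$pigment_id[j],
          mg_mg_distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pigment_a = character(), pigment_b = character(),
                      mg_mg_distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out[order(out$mg_mg_distance), , drop = FALSE]
}

## five fastest inner/outer interface pairs by direct evaluation of the rate
## formula (C = 32.26, n = 1.55, R in nm)
plantedPairTruth <- function(model, rings) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  ring <- rings$ring[match(chl$chain_id, rings$chain_id)]
  inner <- which(ring == "inner"); outer <- which(ring == "outer")
  empty <- data.frame(donor = character(), acceptor = character(),
                      R = numeric(), rate = numeric(), stringsAsFactors = FALSE)
  if (!length(inner) || !length(outer)) return(empty)
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  nb <- as.matrix(chl[, c("nb_x", "nb_y", "nb_z")])
  nd <- as.matrix(chl[, c("nd_x", "nd_y", "nd_z")])
  u <- (nd - nb) / rowNorms(nd - nb)
  rows <- list()
  for (i in outer) for (j in inner) {
    rv <- xyz[j, ] - xyz[i, ]
    R <- sqrt(sum(rv^2))
    if (R > 23) next
    rh <- rv / R
    k <- sum(u[i, ] * u[j, ]) - 3 * sum(u[i, ] * rh) * sum(u[j, ] * rh)
    rate <- 32.26 * k^2 / (1.55^4 * (R / 10)^6)
    rows[[length(rows) + 1]] <- data.frame(
      donor = chl$pigment_id[i], acceptor = chl$pigment_id[j], R = R,
      rate = rate, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$rate), , drop = FALSE]
  utils::head(tab, 5)
}

#' Write a ComplexModel as a standard structure file
#'
#' Protein C-alpha atoms become ATOM records; chlorophylls write their MG, NB
#' and ND pseudo-atoms and carotenoids a single centroid atom as HETATM.
#' PDB output requires single-character chain ids and coordinates within the
#' fixed-width fields; violations trigger an automatic fallback to mmCIF with
#' a warning.
#'
#' @param model a \code{ComplexModel}.
#' @param path output path.
#' @param format \code{"mmcif"} (default) or \code{"pdb"}.
#' @return the path actually written (invisibly); may differ in interpretation
#'   from the request when the PDB fallback engages.
#' @export
writeStructure <- function(model, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  at <- structureAtomTable(model)
  if (format == "pdb") {
    bad <- nchar(at$chain_id) > 1 |
      (nrow(at) > 0 & (max(abs(c(at$x, at$y, at$z, 0))) >= 10000 |
                         max(c(at$residue_number, 0L)) > 9999))
    if (any(bad)) {
      warning("model does not fit fixed-width PDB fields ",
              "(multi-character chain ids or coordinate overflow); ",
              "writing mmCIF instead")
      format <- "mmcif"
    }
  }
  if (format == "pdb") writePdbFile(at, path) else writeCifFile(at, path, model@name)
  invisible(path)
}

structureAtomTable <- function(model) {
  a <- atoms(model)
  p <- pigments(model)
  rows <- list()
  if (nrow(a))
    rows[[1]] <- data.frame(group = "ATOM", chain_id = a$chain_id,
                            residue_name = a$residue_name,
                            residue_number = a$residue_number,
                            atom_name = a$atom_name, x = a$x, y = a$y, z = a$z,
                            element = a$element, stringsAsFactors = FALSE)
  if (nrow(p)) {
    chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
    if (nrow(chl)) {
      mk <- function(nm, cols, el) data.frame(
        group = "HETATM", chain_id = chl$chain_id,
        residue_name = chl$residue_name, residue_number = chl$residue_number,
        atom_name = nm, x = chl[[cols[1]]], y = chl[[cols[2]]],
        z = chl[[cols[3]]], element = el, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- mk("MG", c("x", "y", "z"), "MG")
      rows[[length(rows) + 1]] <- mk("NB", c("nb_x", "nb_y", "nb_z"), "N")
      rows[[length(rows) + 1]] <- mk("ND", c("nd_x", "nd_y", "nd_z"), "N")
    }
    car <- p[p$pigment_class == "carotenoid", , drop = FALSE]
    if (nrow(car))
      rows[[length(rows) + 1]] <- data.frame(
        group = "HETATM", chain_id = car$chain_id,
        residue_name = car$residue_name, residue_number = car$residue_number,
        atom_name = "C1", x = car$x, y = car$y, z = car$z, element = "C",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(group = character(), chain_id = character(),
                      residue_name = character(), residue_number = integer(),
                      atom_name = character(), x = numeric(), y = numeric(),
                      z = numeric(), element = character(),
                      stringsAsFactors = FALSE))
  at <- do.call(rbind, rows)
  at[order(at$chain_id, at$residue_number, at$atom_name), , drop = FALSE]
}

writePdbFile <- function(at, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(at)) {
    nm <- ifelse(nchar(at$element) == 2, sprintf("%-4s", at$atom_name),
                 sprintf(" %-3s", at$atom_name))
    lines <- sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$group, seq_len(nrow(at)) %% 100000, nm, at$residue_name,
      at$chain_id, at$residue_number, at$x, at$y, at$z, 1, 0, at$element)
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

writeCifFile <- function(at, path, name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", gsub("[^A-Za-z0-9_-]", "_", name)), "#",
               "loop_",
               paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                       "label_atom_id", "label_alt_id",
                                       "label_comp_id", "label_asym_id",
                                       "label_seq_id", "Cartn_x", "Cartn_y",
                                       "Cartn_z", "occupancy",
                                       "B_iso_or_equiv", "auth_seq_id",
                                       "auth_asym_id"))), con)
  if (nrow(at)) {
    lines <- sprintf("%-6s %d %s %s . %s %s %d %.4f %.4f %.4f 1.00 0.00 %d %s",
                     at$group, seq_len(nrow(at)), at$element, at$atom_name,
                     at$residue_name, at$chain_id, at$residue_number,
                     at$x, at$y, at$z, at$residue_number, at$chain_id)
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}

#' Apply an exact rigid perturbation to a model
#'
#' Rotates the named chains (default: all) about an axis through a center,
#' then translates them, optionally followed by Gaussian coordinate noise.
#' Used to plant known transforms for superposition and shift recovery.
#'
#' @param model a \code{ComplexModel}.
#' @param rotation_deg rotation angle, degrees.
#' @param axis rotation axis (3-vector).
#' @param center rotation center; default = chlorophyll Mg centroid of the
#'   whole model.
#' @param translation 3-vector, Angstrom.
#' @param chains chain ids to move (default all); unknown ids are an error.
#' @param noise_sd optional Gaussian noise per coordinate, Angstrom.
#' @param seed RNG seed for the noise.
#' @return the perturbed \code{ComplexModel}.
#' @export
perturbComplex <- function(model, rotation_deg = 0, axis = c(0, 0, 1),
                           center = NULL, translation = c(0, 0, 0),
                           chains = NULL, noise_sd = 0, seed = 1L) {
  s <- subunits(model)
  if (is.null(chains)) chains <- s$chain_id
  unknown <- setdiff(chains, s$chain_id)
  if (length(unknown))
    stop("unknown subunit(s): ", paste(unknown, collapse = ", "))
  if (is.null(center)) {
    mg <- chlMgMatrix(model)
    center <- if (nrow(mg)) colMeans(mg) else c(0, 0, 0)
  }
  R <- rotationMatrix(rotation_deg, axis)
  move <- function(m) {
    sweep(sweep(m, 2, center) %*% t(R), 2, center + translation, "+")
  }
  a <- atoms(model); p <- pigments(model)
  sel_a <- a$chain_id %in% chains
  if (any(sel_a)) a[sel_a, c("x", "y", "z")] <-
      move(as.matrix(a[sel_a, c("x", "y", "z")]))
  sel_p <- p$chain_id %in% chains
  if (any(sel_p)) {
    for (cols in list(c("x", "y", "z"), c("nb_x", "nb_y", "nb_z"),
                      c("nd_x", "nd_y", "nd_z"))) {
      m <- as.matrix(p[sel_p, cols])
      ok <- stats::complete.cases(m)
      if (any(ok)) m[ok, ] <- move(m[ok, , drop = FALSE])
      p[sel_p, cols] <- m
    }
  }
  if (noise_sd > 0) {
    out <- withSeed(seed, {
      a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(a), sd = noise_sd), ncol = 3)
      list(a = a)
    })
    a <- out$a
  }
  ComplexModel(model@name, s, p, a)
}

#' Subset a model to named chains
#'
#' @param model a \code{ComplexModel}.
#' @param chains chain ids to keep.
#' @param name name for the subset model.
#' @return a \code{ComplexModel}.
#' @export
subsetChains <- function(model, chains, name = modelName(model)) {
  s <- subunits(model); p <- pigments(model); a <- atoms(model)
  unknown <- setdiff(chains, s$chain_id)
  if (length(unknown))
    stop("unknown subunit(s): ", paste(unknown, collapse = ", "))
  ComplexModel(name, s[s$chain_id %in% chains, , drop = FALSE],
               p[p$chain_id %in% chains, , drop = FALSE],
               a[a$chain_id %in% chains, , drop = FALSE])
}
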