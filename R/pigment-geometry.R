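## Membrane frame, sidedness, ring assignment and interfacial pairs.

chlMgMatrix <- function(model) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  as.matrix(chl[, c("x", "y", "z")])
}

subunitCentroid <- function(model, chain) {
  a <- atoms(model)
  sel <- a[a$chain_id == chain, c("x", "y", "z"), drop = FALSE]
  if (nrow(sel)) return(colMeans(sel))
  p <- pigments(model)
  sel <- p[p$chain_id == chain, c("x", "y", "z"), drop = FALSE]
  if (nrow(sel)) return(colMeans(as.matrix(sel)))
  stop("subunit ", chain, " has neither C-alpha atoms nor pigments")
}

subunitCentroids <- function(model, chains) {
  t(vapply(chains, function(ch) subunitCentroid(model, ch), numeric(3)))
}

#' Estimate the membrane frame of a complex
#'
#' The membrane normal is the direction of least spread of the chlorophyll Mg
#' positions (smallest principal component of their covariance): antenna and
#' core chlorophylls lie in a slab parallel to the membrane. The sign is
#' chosen so that the centroid of the cytoplasmic extrinsic marker subunits
#' (PsaC/PsaD/PsaE by default) projects to the positive side; without markers
#' an explicit \code{positive_point} must be supplied. The midplane splits the
#' projected Mg positions at the midpoint of the gap between the two layers
#' found by a deterministic 1-D two-means split.
#'
#' @param model a \code{ComplexModel} with at least 3 chlorophylls.
#' @param marker_roles roles whose subunits mark the cytoplasmic side.
#' @param positive_point optional 3-vector known to lie on the cytoplasmic
#'   side, used when no marker subunit is present.
#' @return a \code{\linkS4class{MembraneFrame}}.
#' @export
membraneFrame <- function(model, marker_roles = c("PsaC", "PsaD", "PsaE"),
                          positive_point = NULL) {
  mg <- chlMgMatrix(model)
  if (nrow(mg) < 3)
    stop("membrane frame requires at least 3 chlorophylls; got ", nrow(mg))
  ev <- eigen(stats::cov(mg), symmetric = TRUE)
  normal <- ev$vectors[, 3]          # smallest principal component
  center <- colMeans(mg)
  s <- subunits(model)
  markers <- s$chain_id[s$role %in% marker_roles]
  if (length(markers)) {
    mcen <- colMeans(subunitCentroids(model, markers))
    ref <- mcen
  } else if (!is.null(positive_point)) {
    ref <- positive_point
  } else {
    stop("no marker subunits (", paste(marker_roles, collapse = "/"),
         ") present and no positive_point given: cannot fix the ",
         "cytoplasmic sign of the normal")
  }
  if (sum((ref - center) * normal) < 0) normal <- -normal
  proj <- as.numeric(mg %*% normal)
  offset <- twoMeansGapSplit(proj)
  MembraneFrame(normal, offset)
}

#' Classify pigments by membrane side
#'
#' A pigment whose position projects onto the normal at or above the midplane
#' offset is cytoplasmic (ties go to the cytoplasmic side), otherwise lumenal.
#'
#' @param model a \code{ComplexModel}.
#' @param frame a \code{MembraneFrame}.
#' @param classes pigment classes to classify (default chlorophyll a only).
#' @param roles optional subunit-role filter (e.g. \code{"isia"}).
#' @return list with \code{labels} (data.frame \code{pigment_id},
#'   \code{side}) and \code{counts} (named integer vector, cytoplasmic /
#'   lumenal).
#' @export
classifySidedness <- function(model, frame, classes = "chlorophyll_a",
                              roles = NULL) {
  p <- pigments(model)
  p <- p[p$pigment_class %in% classes, , drop = FALSE]
  if (!is.null(roles)) {
    s <- subunits(model)
    p <- p[s$role[match(p$chain_id, s$chain_id)] %in% roles, , drop = FALSE]
  }
  proj <- as.matrix(p[, c("x", "y", "z")]) %*% frame@normal
  side <- ifelse(proj - frame@midplaneOffset >= 0, "cytoplasmic", "lumenal")
  labels <- data.frame(pigment_id = p$pigment_id, side = as.character(side),
                       stringsAsFactors = FALSE)
  counts <- c(cytoplasmic = sum(side == "cytoplasmic"),
              lumenal = sum(side == "lumenal"))
  list(labels = labels, counts = counts)
}

#' Assign antenna subunits to inner/outer rings and index them
#'
#' Radial distances of antenna (isia) subunit centroids from the central axis
#' (the membrane normal through the chlorophyll centroid) are split into two
#' groups at the largest gap in the sorted radii; if the radial spread is too
#' small to support two groups the result is flagged as a single ring (all
#' inner) rather than raising an error. Within each ring, indices run
#' anticlockwise as viewed from the lumenal side, starting from the reference
#' subunit: an explicit \code{reference_chain}, else the antenna subunit
#' closest in angle to a PsaK subunit (the PsaK pole), else the subunit at the
#' smallest angle.
#'
#' @param model a \code{ComplexModel} with antenna subunits.
#' @param frame a \code{MembraneFrame}.
#' @param rings optional explicit override: named list
#'   \code{list(inner = chains, outer = chains)}.
#' @param reference_chain optional chain id fixing index 1.
#' @param min_gap minimum radial gap (Angstrom) required to declare two rings.
#' @return the model with updated \code{ring}/\code{ring_index}; attribute
#'   \code{"single_ring"} on the subunit slot is \code{TRUE} when only one
#'   radial group was found.
#' @export
assignRings <- function(model, frame, rings = NULL, reference_chain = NULL,
                        min_gap = 5) {
  s <- subunits(model)
  isia <- sort(s$chain_id[s$role == "isia"])
  if (!length(isia)) stop("no antenna (isia) subunits in model")
  ## axis center: centroid of the antenna chlorophylls (the ring system being
  ## split); core pigments would bias it off the ring axis
  p <- pigments(model)
  mg <- as.matrix(p[p$pigment_class == "chlorophyll_a" &
                      p$chain_id %in% isia, c("x", "y", "z"), drop = FALSE])
  if (!nrow(mg)) mg <- chlMgMatrix(model)
  center <- if (nrow(mg)) colMeans(mg) else colMeans(subunitCentroids(model, isia))
  cen <- subunitCentroids(model, isia)
  n <- frame@normal
  rel <- sweep(cen, 2, center)
  radial <- rel - (rel %*% n) %*% t(n)
  radii <- rowNorms(radial)

  single <- FALSE
  if (!is.null(rings)) {
    ring <- ifelse(isia %in% rings$inner, "inner",
                   ifelse(isia %in% rings$outer, "outer", "none"))
  } else if (length(isia) == 1L || diff(range(radii)) < min_gap) {
    ring <- rep("inner", length(isia))
    single <- TRUE
  } else {
    o <- order(radii)
    gaps <- diff(radii[o])
    cut <- which.max(gaps)
    if (gaps[cut] < min_gap) {
      ring <- rep("inner", length(isia))
      single <- TRUE
    } else {
      thr <- (radii[o][cut] + radii[o][cut + 1]) / 2
      ring <- ifelse(radii < thr, "inner", "outer")
    }
  }

  ang <- lumenalViewAngles(cen, n, center)
  if (is.null(reference_chain) &&
      !is.na(refcfg <- attr(model, "reference_chain") %||% NA_character_))
    reference_chain <- refcfg
  ref_angle <- 0
  if (!is.null(reference_chain)) {
    if (!reference_chain %in% isia)
      stop("reference_chain ", reference_chain, " is not an antenna subunit")
    ref_angle <- ang[match(reference_chain, isia)]
  } else {
    psak <- sort(s$chain_id[s$role == "PsaK"])
    if (length(psak)) {
      kang <- lumenalViewAngles(subunitCentroids(model, psak), n, center)
      ## antenna subunit nearest in angle to the first PsaK pole
      d <- abs((ang - kang[1] + pi) %% (2 * pi) - pi)
      ref_angle <- ang[which.min(d)]
    } else {
      ref_angle <- min(ang)
    }
  }
  rel_ang <- (ang - ref_angle) %% (2 * pi)

  s$ring[match(isia, s$chain_id)] <- ring
  s$ring_index <- NA_integer_
  for (rg in unique(ring[ring != "none"])) {
    chains_r <- isia[ring == rg]
    ord <- order(rel_ang[ring == rg])
    s$ring_index[match(chains_r[ord], s$chain_id)] <-
      seq_along(chains_r)
  }
  if (single)
    message("only one radial group detected: all antenna subunits ",
            "assigned to the inner ring")
  attr(s, "single_ring") <- single
  out <- ComplexModel(model@name, s, pigments(model), atoms(model))
  attr(out@subunits, "single_ring") <- single
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pairCategory <- function(sub, chain_a, chain_b) {
  ia <- match(chain_a, sub$chain_id); ib <- match(chain_b, sub$chain_id)
  ra <- sub$role[ia]; rb <- sub$role[ib]
  ga <- sub$ring[ia]; gb <- sub$ring[ib]
  cat <- rep("other", length(chain_a))
  both_isia <- ra == "isia" & rb == "isia"
  cat[both_isia & ga != gb & ga != "none" & gb != "none"] <- "inner_outer"
  core_a <- isCoreRole(ra); core_b <- isCoreRole(rb)
  inner_a <- ra == "isia" & ga == "inner"; inner_b <- rb == "isia" & gb == "inner"
  cat[(core_a & inner_b) | (core_b & inner_a)] <- "core_inner"
  cat
}

#' Detect interfacial chlorophyll pairs
#'
#' All chlorophyll pairs from different subunits with Mg-Mg distance at or
#' below the pair cutoff (boundary inclusive at the cutoff, per the reporting
#' convention "<= 23 A"); pairs strictly under the highlight cutoff
#' ("under 18 A") are flagged. Results are sorted by distance.
#'
#' @param model a \code{ComplexModel} (ring assignment required when the
#'   \code{"inner_outer"} category is requested).
#' @param thresholds a \code{\link{GeometryThresholds}}.
#' @param categories categories to keep: any of \code{"inner_outer"},
#'   \code{"core_inner"}, \code{"other"}.
#' @return data.frame: \code{pigment_a}, \code{pigment_b}, \code{chain_a},
#'   \code{chain_b}, \code{mg_mg_distance}, \code{category},
#'   \code{highlight}.
#' @export
interfacialPairs <- function(model, thresholds = GeometryThresholds(),
                             categories = c("inner_outer", "core_inner",
                                            "other")) {
  categories <- match.arg(categories, several.ok = TRUE)
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  empty <- data.frame(pigment_a = character(), pigment_b = character(),
                      chain_a = character(), chain_b = character(),
                      mg_mg_distance = numeric(), category = character(),
                      highlight = logical(), stringsAsFactors = FALSE)
  if (nrow(chl) < 2) return(empty)
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d <= thresholds@pairCutoff, arr.ind = TRUE)
  if (!nrow(sel)) return(empty)
  i <- sel[, 1]; j <- sel[, 2]
  diff_sub <- chl$chain_id[i] != chl$chain_id[j]
  i <- i[diff_sub]; j <- j[diff_sub]
  if (!length(i)) return(empty)
  dist_ij <- d[cbind(i, j)]
  cat <- pairCategory(subunits(model), chl$chain_id[i], chl$chain_id[j])
  out <- data.frame(pigment_a = chl$pigment_id[i],
                    pigment_b = chl$pigment_id[j],
                    chain_a = chl$chain_id[i], chain_b = chl$chain_id[j],
                    mg_mg_distance = dist_ij, category = cat,
                    highlight = dist_ij < thresholds@highlightCutoff,
                    stringsAsFactors = FALSE)
  out <- out[out$category %in% categories, , drop = FALSE]
  out <- out[order(out$mg_mg_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
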