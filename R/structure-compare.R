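## Kabsch superposition and inter-structure comparison: per-subunit shifts,
## ring rotation angles, curvature profiles.

kabsch <- function(A, B) {
  ## optimal proper rotation/translation mapping B onto A (n x 3 each)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- unname(ca - as.numeric(R %*% cb))
  fit <- sweep(B %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  new("RigidTransform", rotation = R, translation = t_vec, rmsd = rmsd,
      nAtoms = nrow(A))
}

referenceChainAtoms <- function(model, role, chain = NULL) {
  s <- subunits(model)
  chains <- if (is.null(chain)) s$chain_id[s$role == role] else chain
  if (!length(chains) || anyNA(chains))
    stop("reference subunit with role ", role, " not found in model ",
         modelName(model))
  chains
}

#' Superpose one complex onto another on a reference core subunit
#'
#' Least-squares (Kabsch) rigid superposition of model B onto model A using
#' the C-alpha atoms of a reference core subunit (PsaA by default), matched by
#' residue number. When a model contains several copies of the reference
#' subunit (a trimeric core), every chain pairing is tried and the best-RMSD
#' pairing is returned unless explicit chains are named. Reflections are
#' rejected.
#'
#' @param model_a,model_b \code{ComplexModel}s.
#' @param reference_role subunit role used for alignment (default
#'   \code{"PsaA"}).
#' @param chain_a,chain_b optional explicit chain ids overriding the
#'   best-RMSD choice.
#' @return a \code{\linkS4class{RigidTransform}} mapping B onto A, with an
#'   attribute \code{"chains"} naming the chain pairing used.
#' @export
superposeOnReference <- function(model_a, model_b, reference_role = "PsaA",
                                 chain_a = NULL, chain_b = NULL) {
  chains_a <- referenceChainAtoms(model_a, reference_role, chain_a)
  chains_b <- referenceChainAtoms(model_b, reference_role, chain_b)
  aa <- atoms(model_a); ab <- atoms(model_b)
  best <- NULL
  for (ca in chains_a) for (cb in chains_b) {
    sa <- aa[aa$chain_id == ca, , drop = FALSE]
    sb <- ab[ab$chain_id == cb, , drop = FALSE]
    common <- intersect(sa$residue_number, sb$residue_number)
    if (length(common) < 3) next
    A <- as.matrix(sa[match(common, sa$residue_number), c("x", "y", "z")])
    B <- as.matrix(sb[match(common, sb$residue_number), c("x", "y", "z")])
    tr <- kabsch(A, B)
    if (is.null(best) || tr@rmsd < best@rmsd) {
      best <- tr
      attr(best, "chains") <- c(a = ca, b = cb)
    }
  }
  if (is.null(best))
    stop("fewer than 3 matched C-alpha atoms between reference subunits (",
         reference_role, ")")
  best
}

matchedIsiaChains <- function(model_a, model_b, by = c("ring", "chain")) {
  by <- match.arg(by)
  sa <- subunits(model_a); sb <- subunits(model_b)
  ia <- sa[sa$role == "isia", , drop = FALSE]
  ib <- sb[sb$role == "isia", , drop = FALSE]
  if (by == "chain") {
    common <- intersect(ia$chain_id, ib$chain_id)
    unmatched <- setdiff(union(ia$chain_id, ib$chain_id), common)
    m <- data.frame(ring = ia$ring[match(common, ia$chain_id)],
                    ring_index = ia$ring_index[match(common, ia$chain_id)],
                    chain_a = common, chain_b = common,
                    stringsAsFactors = FALSE)
  } else {
    ka <- paste(ia$ring, ia$ring_index)
    kb <- paste(ib$ring, ib$ring_index)
    common <- intersect(ka[ia$ring != "none"], kb[ib$ring != "none"])
    unmatched <- c(ia$chain_id[!ka %in% common & ia$ring != "none"],
                   ib$chain_id[!kb %in% common & ib$ring != "none"])
    m <- data.frame(ring = ia$ring[match(common, ka)],
                    ring_index = ia$ring_index[match(common, ka)],
                    chain_a = ia$chain_id[match(common, ka)],
                    chain_b = ib$chain_id[match(common, kb)],
                    stringsAsFactors = FALSE)
  }
  if (length(unmatched))
    warning("unmatched antenna subunits skipped: ",
            paste(unmatched, collapse = ", "))
  m[order(m$ring, m$ring_index), , drop = FALSE]
}

#' Per-subunit displacements between two complexes
#'
#' After applying the superposition transform to model B, the displacement of
#' each matched antenna subunit centroid is decomposed into a signed vertical
#' component along the membrane normal (+ = toward the cytoplasm) and an
#' in-plane horizontal component. total^2 = horizontal^2 + vertical^2.
#'
#' @param model_a,model_b ring-assigned \code{ComplexModel}s.
#' @param transform \code{RigidTransform} mapping B onto A (from
#'   \code{\link{superposeOnReference}}).
#' @param frame \code{MembraneFrame} of model A.
#' @param by match subunits by \code{"ring"} (ring + index, default) or by
#'   \code{"chain"} id.
#' @return data.frame: \code{ring}, \code{ring_index}, \code{chain_a},
#'   \code{chain_b}, \code{horizontal}, \code{vertical}, \code{total}
#'   (Angstrom).
#' @export
subunitShifts <- function(model_a, model_b, transform, frame,
                          by = c("ring", "chain")) {
  m <- matchedIsiaChains(model_a, model_b, by)
  if (!nrow(m))
    return(data.frame(ring = character(), ring_index = integer(),
                      chain_a = character(), chain_b = character(),
                      horizontal = numeric(), vertical = numeric(),
                      total = numeric(), stringsAsFactors = FALSE))
  ca <- subunitCentroids(model_a, m$chain_a)
  cb <- applyTransform(subunitCentroids(model_b, m$chain_b), transform)
  disp <- cb - ca
  vertical <- as.numeric(disp %*% frame@normal)
  total <- rowNorms(disp)
  horizontal <- sqrt(pmax(0, total^2 - vertical^2))
  data.frame(ring = m$ring, ring_index = m$ring_index,
             chain_a = m$chain_a, chain_b = m$chain_b,
             horizontal = horizontal, vertical = vertical, total = total,
             stringsAsFactors = FALSE)
}

#' In-plane ring rotation angle between two complexes
#'
#' Best-fit rotation about the membrane axis mapping the in-plane projections
#' of model B's subunit centroids (after superposition) onto model A's:
#' a 2-D orthogonal Procrustes problem restricted to rotation. Positive
#' angles are anticlockwise as viewed from the lumenal side. The mean of the
#' per-subunit angular offsets is attached as attribute
#' \code{"per_subunit_mean"}.
#'
#' @param model_a,model_b ring-assigned \code{ComplexModel}s.
#' @param transform \code{RigidTransform} mapping B onto A.
#' @param frame \code{MembraneFrame} of model A.
#' @param ring which antenna ring to compare (\code{"outer"}, \code{"inner"})
#'   or \code{"both"}.
#' @param by subunit matching rule, see \code{\link{subunitShifts}}.
#' @return signed angle in degrees.
#' @export
ringRotationAngle <- function(model_a, model_b, transform, frame,
                              ring = c("outer", "inner", "both"),
                              by = c("ring", "chain")) {
  ring <- match.arg(ring)
  m <- matchedIsiaChains(model_a, model_b, match.arg(by))
  if (ring != "both") m <- m[m$ring == ring, , drop = FALSE]
  if (nrow(m) < 2)
    stop("ring rotation requires at least 2 matched subunits; got ", nrow(m))
  ca <- subunitCentroids(model_a, m$chain_a)
  cb <- applyTransform(subunitCentroids(model_b, m$chain_b), transform)
  b <- lumenalViewBasis(frame@normal)
  proj <- function(x) cbind(x %*% b$e1, x %*% b$e2)
  pa <- proj(ca); pb <- proj(cb)
  pa <- sweep(pa, 2, colMeans(pa)); pb <- sweep(pb, 2, colMeans(pb))
  ## rotation theta applied to B projections to best match A
  num <- sum(pb[, 1] * pa[, 2] - pb[, 2] * pa[, 1])
  den <- sum(pb[, 1] * pa[, 1] + pb[, 2] * pa[, 2])
  theta <- atan2(num, den) * 180 / pi
  ang_a <- atan2(pa[, 2], pa[, 1]); ang_b <- atan2(pb[, 2], pb[, 1])
  per <- ((ang_a - ang_b + pi) %% (2 * pi) - pi) * 180 / pi
  structure(theta, per_subunit_mean = mean(per))
}

#' Vertical curvature profile of the antenna rings
#'
#' Per antenna subunit: angular position (lumenal-view convention, degrees)
#' and vertical offset of its centroid relative to the core centroid along
#' the membrane normal. The per-ring peak-to-peak offset summarizes how far
#' the membrane-spanning region deviates from a flat slab.
#'
#' @param model a ring-assigned \code{ComplexModel}.
#' @param frame a \code{MembraneFrame}.
#' @return list with \code{profile} (data.frame: ring, ring_index, chain,
#'   angle_deg, vertical_offset) and \code{peak_to_peak} (named numeric per
#'   ring).
#' @export
curvatureProfile <- function(model, frame) {
  s <- subunits(model)
  isia <- s[s$role == "isia", , drop = FALSE]
  if (!nrow(isia)) stop("no antenna subunits in model")
  core <- s$chain_id[isCoreRole(s$role)]
  ref_cen <- if (length(core)) colMeans(subunitCentroids(model, core))
             else colMeans(chlMgMatrix(model))
  cen <- subunitCentroids(model, isia$chain_id)
  vert <- as.numeric(sweep(cen, 2, ref_cen) %*% frame@normal)
  ang <- lumenalViewAngles(cen, frame@normal, ref_cen) * 180 / pi
  prof <- data.frame(ring = isia$ring, ring_index = isia$ring_index,
                     chain = isia$chain_id, angle_deg = ang,
                     vertical_offset = vert, stringsAsFactors = FALSE)
  prof <- prof[order(prof$ring, prof$ring_index), , drop = FALSE]
  rownames(prof) <- NULL
  ptp <- vapply(split(prof$vertical_offset, prof$ring),
                function(v) diff(range(v)), numeric(1))
  list(profile = prof, peak_to_peak = ptp)
}
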