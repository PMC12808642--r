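#' @import methods
NULL

CORE_ROLE_PATTERN <- "^Psa[A-Z]$"

isCoreRole <- function(role) grepl(CORE_ROLE_PATTERN, role)

emptyAtoms <- function() {
  data.frame(chain_id = character(), residue_name = character(),
             residue_number = integer(), atom_name = character(),
             x = numeric(), y = numeric(), z = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

emptyPigments <- function() {
  data.frame(pigment_id = character(), chain_id = character(),
             residue_number = integer(), residue_name = character(),
             pigment_class = character(),
             x = numeric(), y = numeric(), z = numeric(),
             nb_x = numeric(), nb_y = numeric(), nb_z = numeric(),
             nd_x = numeric(), nd_y = numeric(), nd_z = numeric(),
             stringsAsFactors = FALSE)
}

emptySubunits <- function() {
  data.frame(chain_id = character(), role = character(),
             ring = character(), ring_index = integer(),
             stringsAsFactors = FALSE)
}

#' ComplexModel: a parsed pigment-protein complex
#'
#' Holds the normalized records extracted from an atomic model: one row per
#' protein subunit (chain), one row per pigment cofactor, and the retained
#' protein C-alpha atoms used for centroids and superposition.
#'
#' Chlorophyll rows carry the central Mg position in \code{x,y,z} and the
#' NB/ND nitrogen positions used to derive the Qy transition dipole;
#' carotenoid rows carry a representative centroid in \code{x,y,z} and
#' \code{NA} dipole atoms.
#'
#' @slot name character model name.
#' @slot subunits data.frame with columns \code{chain_id}, \code{role}
#'   (\code{"PsaA"}-style core names, \code{"isia"}, or \code{"other"}),
#'   \code{ring} (\code{"inner"}, \code{"outer"} or \code{"none"}) and
#'   \code{ring_index}.
#' @slot pigments data.frame, one row per cofactor (see above).
#' @slot atoms data.frame of protein C-alpha atoms.
#' @export
setClass("ComplexModel",
  representation(name = "character", subunits = "data.frame",
                 pigments = "data.frame", atoms = "data.frame"),
  prototype(name = "complex", subunits = emptySubunits(),
            pigments = emptyPigments(), atoms = emptyAtoms()))

validComplexModel <- function(object) {
  msg <- character()
  p <- object@pigments
  s <- object@subunits
  if (anyDuplicated(p$pigment_id))
    msg <- c(msg, "pigment_id values must be unique")
  if (nrow(p) && !all(p$chain_id %in% s$chain_id))
    msg <- c(msg, "every pigment chain_id must resolve to a listed subunit")
  if (nrow(p)) {
    chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
    if (nrow(chl)) {
      co <- as.matrix(chl[, c("x", "y", "z", "nb_x", "nb_y", "nb_z",
                              "nd_x", "nd_y", "nd_z")])
      if (!all(is.finite(co)))
        msg <- c(msg, "chlorophyll records must have finite Mg/NB/ND coordinates")
      else {
        same <- rowSums((as.matrix(chl[, c("nb_x", "nb_y", "nb_z")]) -
                         as.matrix(chl[, c("nd_x", "nd_y", "nd_z")]))^2) == 0
        if (any(same))
          msg <- c(msg, paste("degenerate dipole (NB == ND) for:",
                              paste(chl$pigment_id[same], collapse = ", ")))
      }
    }
    if (!all(is.finite(as.matrix(p[, c("x", "y", "z")]))))
      msg <- c(msg, "pigment positions must be finite")
  }
  if (nrow(s)) {
    bad <- s$ring != "none" & s$role != "isia"
    if (any(bad))
      msg <- c(msg, "ring may be set only for antenna (isia) subunits")
    for (rg in c("inner", "outer")) {
      idx <- s$ring_index[s$ring == rg & !is.na(s$ring_index)]
      if (anyDuplicated(idx))
        msg <- c(msg, sprintf("ring_index not unique within %s ring", rg))
    }
  }
  if (nrow(object@atoms) &&
      !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "atom positions must be finite")
  if (length(msg)) msg else TRUE
}

setValidity("ComplexModel", validComplexModel)

#' Construct a ComplexModel
#'
#' @param name model name.
#' @param subunits,pigments,atoms data.frames following the schemas described
#'   in \code{\linkS4class{ComplexModel}}; missing columns of empty inputs are
#'   filled with empty defaults.
#' @return a validated \code{ComplexModel}.
#' @export
ComplexModel <- function(name = "complex", subunits = emptySubunits(),
                         pigments = emptyPigments(), atoms = emptyAtoms()) {
  if (!nrow(subunits)) subunits <- emptySubunits()
  if (!nrow(pigments)) pigments <- emptyPigments()
  if (!nrow(atoms)) atoms <- emptyAtoms()
  rownames(subunits) <- NULL; rownames(pigments) <- NULL; rownames(atoms) <- NULL
  new("ComplexModel", name = name, subunits = subunits,
      pigments = pigments, atoms = atoms)
}

#' MembraneFrame: membrane normal, midplane and sidedness convention
#'
#' The normal is a unit vector; positions projecting above
#' \code{midplaneOffset} along it are on the positive side, which is fixed to
#' the cytoplasmic face of the thylakoid membrane.
#'
#' @slot normal unit 3-vector.
#' @slot midplaneOffset signed distance (Angstrom) of the midplane from the
#'   origin along the normal.
#' @slot positiveSide fixed to \code{"cytoplasmic"}.
#' @export
setClass("MembraneFrame",
  representation(normal = "numeric", midplaneOffset = "numeric",
                 positiveSide = "character"),
  prototype(normal = c(0, 0, 1), midplaneOffset = 0,
            positiveSide = "cytoplasmic"))

setValidity("MembraneFrame", function(object) {
  msg <- character()
  if (length(object@normal) != 3 || !all(is.finite(object@normal)))
    msg <- c(msg, "normal must be a finite 3-vector")
  else if (abs(vecNorm(object@normal) - 1) > 1e-9)
    msg <- c(msg, "normal must be a unit vector (|n| = 1 within 1e-9)")
  if (!identical(object@positiveSide, "cytoplasmic"))
    msg <- c(msg, "positiveSide is fixed to 'cytoplasmic'")
  if (length(msg)) msg else TRUE
})

#' @rdname MembraneFrame-class
#' @param normal unit 3-vector (positive direction = cytoplasmic).
#' @param midplaneOffset scalar Angstrom.
#' @return a \code{MembraneFrame}.
#' @export
MembraneFrame <- function(normal = c(0, 0, 1), midplaneOffset = 0) {
  new("MembraneFrame", normal = unitVector(normal),
      midplaneOffset = midplaneOffset, positiveSide = "cytoplasmic")
}

#' GeometryThresholds: Mg-Mg distance cutoffs for interfacial pairs
#'
#' Pairs at Mg-Mg distance <= \code{pairCutoff} are reported; pairs strictly
#' under \code{highlightCutoff} are flagged as highlighted (the short contacts
#' drawn with red arrows in structure figures).
#'
#' @slot pairCutoff Angstrom, default 23.
#' @slot highlightCutoff Angstrom, default 18.
#' @export
setClass("GeometryThresholds",
  representation(pairCutoff = "numeric", highlightCutoff = "numeric"),
  prototype(pairCutoff = 23, highlightCutoff = 18))

setValidity("GeometryThresholds", function(object) {
  if (object@highlightCutoff <= 0 ||
      object@highlightCutoff > object@pairCutoff)
    "requires 0 < highlightCutoff <= pairCutoff" else TRUE
})

#' @rdname GeometryThresholds-class
#' @param pairCutoff,highlightCutoff Angstrom.
#' @export
GeometryThresholds <- function(pairCutoff = 23, highlightCutoff = 18) {
  new("GeometryThresholds", pairCutoff = pairCutoff,
      highlightCutoff = highlightCutoff)
}

#' FretParameters: constants of the Forster rate expression
#'
#' Rates follow k = C * kappa^2 / (n^4 * R^6) with R the Mg-Mg distance
#' expressed in nanometres, giving rates in ps^-1. C = 32.26 is the Chl a to
#' Chl a spectral-overlap constant and n = 1.55 the refractive index.
#'
#' @slot C spectral-overlap constant (> 0).
#' @slot n refractive index (>= 1).
#' @slot distanceUnit fixed to \code{"nm"}.
#' @export
setClass("FretParameters",
  representation(C = "numeric", n = "numeric", distanceUnit = "character"),
  prototype(C = 32.26, n = 1.55, distanceUnit = "nm"))

setValidity("FretParameters", function(object) {
  msg <- character()
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (!identical(object@distanceUnit, "nm"))
    msg <- c(msg, "distanceUnit is fixed to 'nm'")
  if (length(msg)) msg else TRUE
})

#' @rdname FretParameters-class
#' @param C,n numeric constants.
#' @export
FretParameters <- function(C = 32.26, n = 1.55) {
  ## note: new(Class, C = ...) would partially match C to the Class formal,
  ## so the C slot is assigned explicitly
  obj <- new("FretParameters")
  obj@C <- C
  obj@n <- n
  validObject(obj)
  obj
}

#' PathwayThresholds: lifetime filters for the energy-transfer network
#'
#' @slot displayLifetimeMax ps; edges with lifetime under this are kept in the
#'   displayed network (default 40).
#' @slot fastLifetimeMax ps; edges under this count as fast pathways
#'   (default 20).
#' @export
setClass("PathwayThresholds",
  representation(displayLifetimeMax = "numeric", fastLifetimeMax = "numeric"),
  prototype(displayLifetimeMax = 40, fastLifetimeMax = 20))

setValidity("PathwayThresholds", function(object) {
  if (object@fastLifetimeMax <= 0 ||
      object@fastLifetimeMax > object@displayLifetimeMax)
    "requires 0 < fastLifetimeMax <= displayLifetimeMax" else TRUE
})

#' @rdname PathwayThresholds-class
#' @param displayLifetimeMax,fastLifetimeMax ps.
#' @export
PathwayThresholds <- function(displayLifetimeMax = 40, fastLifetimeMax = 20) {
  new("PathwayThresholds", displayLifetimeMax = displayLifetimeMax,
      fastLifetimeMax = fastLifetimeMax)
}

#' RigidTransform: result of a least-squares superposition
#'
#' Maps coordinates of the mobile model onto the reference:
#' \code{x' = rotation \%*\% x + translation}.
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation 3-vector, Angstrom.
#' @slot rmsd root-mean-square deviation over the matched atoms after
#'   superposition, Angstrom.
#' @slot nAtoms number of matched atom pairs.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0,
            nAtoms = 0L))

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(t(R) %*% R - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det = +1); reflections rejected")
  }
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})
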