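#' Accessors for ComplexModel
#'
#' @param x a \code{\linkS4class{ComplexModel}}.
#' @return \code{pigments}, \code{subunits} and \code{atoms} return the
#'   corresponding data.frame; \code{modelName} the name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pigments", function(x) standardGeneric("pigments"))

#' @rdname accessors
#' @export
setGeneric("subunits", function(x) standardGeneric("subunits"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname accessors
#' @export
setMethod("pigments", "ComplexModel", function(x) x@pigments)

#' @rdname accessors
#' @export
setMethod("subunits", "ComplexModel", function(x) x@subunits)

#' @rdname accessors
#' @export
setMethod("atoms", "ComplexModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("modelName", "ComplexModel", function(x) x@name)

setMethod("show", "ComplexModel", function(object) {
  p <- object@pigments
  cat("ComplexModel:", object@name, "\n")
  cat(" ", nrow(object@subunits), "subunits (",
      sum(object@subunits$role == "isia"), "antenna,",
      sum(isCoreRole(object@subunits$role)), "core )\n")
  cat(" ", nrow(p), "pigments (",
      sum(p$pigment_class == "chlorophyll_a"), "Chl a,",
      sum(p$pigment_class == "carotenoid"), "carotenoid )\n")
  cat(" ", nrow(object@atoms), "protein C-alpha atoms\n")
  invisible(object)
})

setMethod("show", "MembraneFrame", function(object) {
  cat("MembraneFrame: normal = (",
      paste(sprintf("%.4f", object@normal), collapse = ", "),
      "), midplane offset =", sprintf("%.2f", object@midplaneOffset),
      "A, positive side =", object@positiveSide, "\n")
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat("RigidTransform:", sprintf("rotation %.3f deg,", ang),
      sprintf("translation |t| = %.3f A,", vecNorm(object@translation)),
      sprintf("RMSD = %.4f A over %d atoms\n", object@rmsd, object@nAtoms))
  invisible(object)
})

## Apply a rigid transform to a coordinate matrix or a whole model.
#' Apply a rigid transform
#'
#' @param x an n x 3 coordinate matrix or a \code{ComplexModel}.
#' @param transform a \code{\linkS4class{RigidTransform}}.
#' @return object of the same type with transformed coordinates.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "ComplexModel", function(x, transform) {
  tr <- function(df, cols) {
    if (!nrow(df)) return(df)
    m <- as.matrix(df[, cols])
    ok <- stats::complete.cases(m)
    if (any(ok))
      df[ok, cols] <- applyTransform(m[ok, , drop = FALSE], transform)
    df
  }
  a <- tr(x@atoms, c("x", "y", "z"))
  p <- tr(x@pigments, c("x", "y", "z"))
  p <- tr(p, c("nb_x", "nb_y", "nb_z"))
  p <- tr(p, c("nd_x", "nd_y", "nd_z"))
  ComplexModel(x@name, x@subunits, p, a)
})
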