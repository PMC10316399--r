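#' Accessors for nanoFRET classes
#'
#' Small accessor generics exposing the slots of the model, configuration,
#' decay and fit classes without direct slot access.
#'
#' @param object a nanoFRET S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("radius", function(object) standardGeneric("radius"))
#' @rdname accessors
#' @export
setGeneric("areaFraction", function(object) standardGeneric("areaFraction"))
#' @rdname accessors
#' @export
setGeneric("boxLength", function(object) standardGeneric("boxLength"))
#' @rdname accessors
#' @export
setGeneric("nDomains", function(object) standardGeneric("nDomains"))
#' @rdname accessors
#' @export
setGeneric("decayTime", function(object) standardGeneric("decayTime"))
#' @rdname accessors
#' @export
setGeneric("decayIntensity", function(object) standardGeneric("decayIntensity"))
#' @rdname accessors
#' @export
setGeneric("decayCounts", function(object) standardGeneric("decayCounts"))
#' @rdname accessors
#' @export
setGeneric("radiusHat", function(object) standardGeneric("radiusHat"))
#' @rdname accessors
#' @export
setGeneric("areaHat", function(object) standardGeneric("areaHat"))
#' @rdname accessors
#' @export
setGeneric("chiSquare", function(object) standardGeneric("chiSquare"))
#' @rdname accessors
#' @export
setGeneric("chiSurface", function(object) standardGeneric("chiSurface"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("bondTable", function(object) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setGeneric("moietyOf", function(object) standardGeneric("moietyOf"))

setMethod("radius", "DomainModel", function(object) object@radius)
setMethod("radius", "DomainConfiguration", function(object) object@radius)
setMethod("areaFraction", "DomainModel", function(object) object@areaFraction)
setMethod("boxLength", "DomainModel", function(object) object@boxLength)
setMethod("boxLength", "DomainConfiguration", function(object) object@boxLength)
setMethod("boxLength", "ProbeConfiguration", function(object) object@boxLength)
setMethod("nDomains", "DomainConfiguration",
          function(object) nrow(object@centers))
setMethod("decayTime", "DecayCurve", function(object) object@time)
setMethod("decayIntensity", "DecayCurve", function(object) object@intensity)
setMethod("decayCounts", "DecayCurve", function(object) object@counts)
setMethod("radiusHat", "FitResult", function(object) object@radiusHat)
setMethod("areaHat", "FitResult", function(object) object@areaHat)
setMethod("chiSquare", "FitResult", function(object) object@chiSquare)
setMethod("chiSurface", "FitResult", function(object) object@surface)
setMethod("atomTable", "Topology", function(object) object@atoms)
setMethod("bondTable", "Topology", function(object) object@bonds)
setMethod("moietyOf", "MoietyMap", function(object) object@labels)

setMethod("show", "DomainModel", function(object) {
  cat(sprintf(
    "DomainModel: R = %.3g nm, A = %.3g, box = %.4g nm, dz = %.3g nm, K_D = %.3g, K_A = %.3g\n",
    object@radius, object@areaFraction, object@boxLength, object@bilayerSep,
    object@partitionDonor, object@partitionAcceptor))
})

setMethod("show", "DomainConfiguration", function(object) {
  cat(sprintf("DomainConfiguration: %d discs of radius %.4g nm in a %.4g nm box (coverage %.3f)\n",
              nrow(object@centers), object@radius, object@boxLength,
              nrow(object@centers) * pi * object@radius^2 / object@boxLength^2))
})

setMethod("show", "ProbeConfiguration", function(object) {
  cat(sprintf("ProbeConfiguration: %d donors (%d in-domain), %d acceptors (%d in-domain), box %.4g nm\n",
              nrow(object@donorXY), sum(object@donorInDomain),
              nrow(object@acceptorXY), sum(object@acceptorInDomain),
              object@boxLength))
})

setMethod("show", "FretParameters", function(object) {
  cat(sprintf("FretParameters: R0 = %.3g nm, tauD = %.3g ns, rMin = %.3g nm\n",
              object@forsterRadius, object@donorLifetime, object@rMin))
})

setMethod("show", "DecayCurve", function(object) {
  kind <- c(if (length(object@intensity)) "intensity",
            if (length(object@counts)) "counts")
  cat(sprintf("DecayCurve: %d channels of %.4g ns (%s)\n",
              length(object@time), object@channelWidth,
              paste(kind, collapse = " + ")))
  if (length(object@counts))
    cat(sprintf("  total counts: %d\n", as.integer(sum(object@counts))))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: R = %.4g nm, A = %.3f, chi2 = %.4g (%d grid nodes)\n",
              object@guvId, object@radiusHat, object@areaHat,
              object@chiSquare, nrow(object@surface)))
})

setMethod("show", "DistributionSummary", function(object) {
  cat(sprintf("DistributionSummary: %d vesicles, <R> = %.4g nm, <A> = %.3f\n",
              length(object@results), object@meanRadius, object@meanArea))
})

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d atoms, %d bonds, %d molecules (%s)\n",
              nrow(object@atoms), nrow(object@bonds),
              length(unique(object@atoms$mol)),
              paste(unique(object@atoms$species), collapse = ", ")))
})

setMethod("show", "MoietyMap", function(object) {
  tab <- table(object@labels)
  cat("MoietyMap:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})
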