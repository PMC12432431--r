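#' @include AllClasses.R
NULL

#' Number of beads in an object
#' @param x a ChainTopology or SimSystem.
#' @return integer bead count.
#' @export
setGeneric("beadCount", function(x) standardGeneric("beadCount"))

#' Number of bonds in an object
#'
#' For a single chain this is the `N` entering the Flory radius-of-gyration
#' relation.
#'
#' @param x a ChainTopology or SimSystem.
#' @return integer bond count.
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))

#' Bead coordinates (nm)
#' @param x a SimSystem or Trajectory.
#' @param ... further arguments for methods.
#' @return numeric matrix (or array for trajectories).
#' @export
setGeneric("coordinates", function(x, ...) standardGeneric("coordinates"))

#' Simulation / profile temperature (K)
#' @param x an object carrying a temperature.
#' @return numeric temperature in K.
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' Time-averaged density profile
#' @param x a DensityProfile.
#' @return numeric vector, mean density per bin over stored frames (g/cm^3).
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))

#' Coexistence points of a binodal dataset
#' @param x a BinodalDataset.
#' @return data.frame of per-temperature dilute/dense densities.
#' @export
setGeneric("coexPoints", function(x) standardGeneric("coexPoints"))

#' Fitted critical point of a binodal dataset
#' @param x a fitted BinodalDataset.
#' @return named numeric c(Tc = K, rhoc = g/cm^3).
#' @export
setGeneric("criticalPoint", function(x) standardGeneric("criticalPoint"))

#' @describeIn beadCount beads of one chain
#' @export
setMethod("beadCount", "ChainTopology", function(x) nrow(x@beads))

#' @describeIn bondCount bonds of one chain
#' @export
setMethod("bondCount", "ChainTopology", function(x) nrow(x@bonds))

#' @describeIn beadCount all beads in the system
#' @export
setMethod("beadCount", "SimSystem", function(x) nrow(x@coordinates))

#' @describeIn bondCount all bonds in the system
#' @export
setMethod("bondCount", "SimSystem",
          function(x) sum(vapply(x@chains, bondCount, integer(1))))

#' @describeIn coordinates positions of all beads, nm
#' @export
setMethod("coordinates", "SimSystem", function(x, ...) x@coordinates)

#' @describeIn coordinates coordinates of one frame (`frame = i`), nm
#' @param frame integer frame index.
#' @export
setMethod("coordinates", "Trajectory", function(x, frame = 1L, ...) {
  if (frame < 1L || frame > dim(x@frames)[1])
    stop("frame index out of range", call. = FALSE)
  x@frames[frame, , , drop = TRUE]
})

#' @describeIn temperature resolution temperature of the system
#' @export
setMethod("temperature", "SimSystem", function(x) x@temperature)

#' @describeIn temperature temperature of the profile
#' @export
setMethod("temperature", "DensityProfile", function(x) x@temperature)

#' @describeIn profileMean time-average over stored frames
#' @export
setMethod("profileMean", "DensityProfile",
          function(x) colMeans(x@densities))

#' @describeIn coexPoints stored coexistence points
#' @export
setMethod("coexPoints", "BinodalDataset", function(x) x@points)

#' @describeIn criticalPoint fitted (Tc, rhoc)
#' @export
setMethod("criticalPoint", "BinodalDataset", function(x) {
  if (!length(x@Tc) || is.na(x@Tc))
    stop("binodal has not been fitted; run fitBinodal()", call. = FALSE)
  c(Tc = x@Tc, rhoc = x@rhoc)
})

setMethod("show", "ChainTopology", function(object) {
  cat(sprintf("ChainTopology: %d beads, %d bonds\n",
              beadCount(object), bondCount(object)))
  s <- object@sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" sequence:", s, "\n")
  cat(sprintf(" net charge: %+.2f e\n", sum(object@beads$charge)))
})

setMethod("show", "SimSystem", function(object) {
  cat(sprintf(
    "SimSystem: %d beads in %d chain(s), box %.2f x %.2f x %.2f nm, %g K\n",
    beadCount(object), length(object@chains), object@box[1], object@box[2],
    object@box[3], object@temperature))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d beads, t = %.3f .. %.3f ps\n",
              dim(object@frames)[1], dim(object@frames)[2],
              min(object@times), max(object@times)))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf(
    "DensityProfile at %g K: %d frames x %d bins, peak %.4f g/cm^3\n",
    object@temperature, nrow(object@densities), ncol(object@densities),
    max(profileMean(object))))
})

setMethod("show", "NuSeries", function(object) {
  cat(sprintf("NuSeries: %d temperatures (%g .. %g K), nu %.3f .. %.3f\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures), min(object@nu), max(object@nu)))
})

setMethod("show", "BinodalDataset", function(object) {
  cat(sprintf("BinodalDataset (%s): %d coexistence points\n",
              object@mode, nrow(object@points)))
  if (length(object@Tc) && !is.na(object@Tc))
    cat(sprintf(" fitted critical point: Tc = %.2f K, rhoc = %.4f g/cm^3\n",
                object@Tc, object@rhoc))
})
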