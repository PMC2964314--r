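#' @import methods
NULL

.isOrthonormal <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Pinhole camera model
#'
#' One camera's projection from 3D lab coordinates to 2D pixel coordinates.
#' World points `X` map through `x_cam = R X + t`, then perspective division
#' and the focal/principal-point affinity; an optional single radial
#' distortion coefficient `k1` is supported but zero by default (synthetic
#' cameras are ideal).
#'
#' Pixel convention: integer coordinates at pixel centers, origin at the
#' top-left pixel, u rightward, v downward.
#'
#' @slot focal numeric(2), focal lengths in pixels (both > 0).
#' @slot principal numeric(2), principal point in pixels.
#' @slot rotation 3x3 orthonormal world-to-camera rotation, det = +1.
#' @slot translation numeric(3), world-to-camera translation (length units).
#' @slot k1 numeric(1), radial distortion coefficient (dimensionless).
#'
#' @seealso [cameraModel()], [projectPoints()], [backProject()]
#' @export
setClass("CameraModel",
  representation(focal = "numeric", principal = "numeric",
                 rotation = "matrix", translation = "numeric",
                 k1 = "numeric"),
  prototype(focal = c(1, 1), principal = c(0, 0),
            rotation = diag(3), translation = c(0, 0, 0), k1 = 0))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (length(object@focal) != 2L || any(object@focal <= 0))
    msg <- c(msg, "focal must be two positive lengths (px)")
  if (length(object@principal) != 2L)
    msg <- c(msg, "principal must have length 2")
  if (!.isOrthonormal(object@rotation))
    msg <- c(msg, "rotation must be orthonormal with det +1")
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(object@k1) != 1L)
    msg <- c(msg, "k1 must be a single number")
  if (length(msg)) msg else TRUE
})

#' 3D ray
#'
#' A ray from a camera center into the scene: `origin + s * direction`,
#' s >= 0, with a unit direction vector.
#'
#' @slot origin numeric(3).
#' @slot direction numeric(3), unit norm.
#' @export
setClass("Ray3D", representation(origin = "numeric", direction = "numeric"))

setValidity("Ray3D", function(object) {
  if (length(object@origin) != 3L || length(object@direction) != 3L)
    return("origin and direction must have length 3")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  TRUE
})

#' Two-view triangulation result
#'
#' The midpoint of the mutual-perpendicular segment between two camera rays,
#' together with the segment length (the triangulation error, a confidence
#' measure for the 2D correspondence).
#'
#' @slot point numeric(3).
#' @slot error numeric(1), >= 0, in world length units.
#' @export
setClass("TriangulationResult",
  representation(point = "numeric", error = "numeric"))

setValidity("TriangulationResult", function(object) {
  if (length(object@point) != 3L) return("point must have length 3")
  if (length(object@error) != 1L || object@error < 0)
    return("error must be a single non-negative number")
  TRUE
})

#' Marker topology of the six-legged preparation
#'
#' The 26-marker layout: six legs (right/left x front/middle/hind), each an
#' ordered proximal-to-distal chain ThC, CTr, FTi, TiTa, plus one extra
#' coxal marker on each front leg (attached between ThC and CTr) used to
#' resolve coxal long-axis rotation. Every non-ThC marker has exactly one
#' proximal neighbour; the chain depth index k is 0 at ThC.
#'
#' @slot markers data.frame with columns `marker`, `leg`, `side` ("R"/"L"),
#'   `pair` ("front"/"middle"/"hind"), `joint`, `depth`, `proximal`.
#' @seealso [hexapodTopology()]
#' @export
setClass("MarkerTopology", representation(markers = "data.frame"))

setValidity("MarkerTopology", function(object) {
  df <- object@markers
  need <- c("marker", "leg", "side", "pair", "joint", "depth", "proximal")
  if (!all(need %in% names(df))) return("missing topology columns")
  if (anyDuplicated(df$marker)) return("duplicate marker names")
  nonroot <- df[df$depth > 0L, ]
  if (!all(nonroot$proximal %in% df$marker))
    return("every non-ThC marker needs a proximal neighbour in the table")
  if (any(is.na(df$depth)) || any(df$depth < 0L))
    return("depths must be non-negative")
  TRUE
})

#' Search ellipsoid for one tracking step
#'
#' A flattened sphere centered at the last known marker position: circular
#' cross-section of radius `longRadius` perpendicular to the short axis, and
#' a short radius of exactly half the long radius along `shortAxis` (the
#' proximal-to-distal leg-segment direction), encoding that leg segments
#' resist length change while joint rotation is unconstrained.
#'
#' @slot center numeric(3).
#' @slot longRadius numeric(1) > 0.
#' @slot shortAxis numeric(3) unit vector (short radius = longRadius / 2).
#' @slot sphere logical(1); TRUE for the degenerate spherical case (ThC, or
#'   coincident proximal point), where all radii equal `longRadius`.
#' @export
setClass("SearchEllipsoid",
  representation(center = "numeric", longRadius = "numeric",
                 shortAxis = "numeric", sphere = "logical"))

setValidity("SearchEllipsoid", function(object) {
  if (length(object@center) != 3L) return("center must have length 3")
  if (object@longRadius <= 0) return("longRadius must be positive")
  if (!object@sphere && abs(sqrt(sum(object@shortAxis^2)) - 1) > 1e-9)
    return("shortAxis must be a unit vector")
  TRUE
})

#' Tracker settings
#'
#' Tunable parameters of the ellipsoid-gated tracker. Lengths are in world
#' units (mm for the default rig).
#'
#' @slot baseRadius long radius r0 of the depth-1 search ellipsoid (mm).
#' @slot depthScale per-depth exponential scale g > 1; long radius = r0 g^k.
#' @slot thcRadius radius of the ThC search sphere (mm).
#' @slot enlargeFactor radius multiplier applied when a centroid is too dim.
#' @slot maxEnlarge maximum number of per-camera enlargement retries.
#' @slot triErrorMax acceptance threshold on the triangulation error (mm).
#' @slot segLenFactor maximum allowed leg-segment length-change factor
#'   (ratio to the segment length at the nearest user-defined frame).
#' @slot dimFraction centroid is "dim" below this fraction of the frame's
#'   median brightness (default 0.5).
#' @slot dimFloor absolute brightness floor for the dim test (intensity
#'   units); keeps the gate active on mostly-zero processed frames.
#' @export
setClass("TrackerSettings",
  representation(baseRadius = "numeric", depthScale = "numeric",
                 thcRadius = "numeric", enlargeFactor = "numeric",
                 maxEnlarge = "integer", triErrorMax = "numeric",
                 segLenFactor = "numeric", dimFraction = "numeric",
                 dimFloor = "numeric"),
  prototype(baseRadius = 1.0, depthScale = 1.3, thcRadius = 0.5,
            enlargeFactor = 2, maxEnlarge = 2L, triErrorMax = 1.0,
            segLenFactor = 1.3, dimFraction = 0.5, dimFloor = 1))

setValidity("TrackerSettings", function(object) {
  ok <- all(c(object@baseRadius, object@thcRadius, object@enlargeFactor,
              object@triErrorMax, object@dimFloor) > 0) &&
    object@depthScale > 1 && object@segLenFactor >= 1 &&
    object@maxEnlarge >= 0L &&
    object@dimFraction > 0 && object@dimFraction < 1
  if (!ok) return("invalid tracker settings (see class documentation)")
  TRUE
})

#' Image filter settings
#'
#' @slot nBackgroundFrames number of evenly spaced frames averaged into the
#'   background image (default 100).
#' @slot backgroundSigma Gaussian standard deviation (px) applied to each
#'   background frame before averaging (default 5).
#' @slot medianWidth width (px, odd) of the median filter applied after
#'   background subtraction (default 5).
#' @export
setClass("FilterSettings",
  representation(nBackgroundFrames = "integer", backgroundSigma = "numeric",
                 medianWidth = "integer"),
  prototype(nBackgroundFrames = 100L, backgroundSigma = 5, medianWidth = 5L))

setValidity("FilterSettings", function(object) {
  if (object@nBackgroundFrames < 1L) return("nBackgroundFrames must be >= 1")
  if (object@backgroundSigma <= 0) return("backgroundSigma must be positive")
  if (object@medianWidth < 1L || object@medianWidth %% 2L == 0L)
    return("medianWidth must be odd and positive")
  TRUE
})

#' Grayscale frame stack
#'
#' A stack of same-sized 8-bit grayscale frames with acquisition metadata.
#' Frames are stored as an integer array indexed `[row, col, frame]`; pixel
#' (u, v) in camera coordinates is element `[v + 1, u + 1]`.
#'
#' @slot frames integer array, nrow x ncol x nframes, values in [0, range].
#' @slot fps frame rate (Hz).
#' @slot mmPerPx approximate world scale hint (mm per pixel).
#' @slot range maximum representable intensity (255 for 8-bit).
#' @export
setClass("FrameStack",
  representation(frames = "array", fps = "numeric", mmPerPx = "numeric",
                 range = "numeric"),
  prototype(fps = 500, mmPerPx = 1 / 3, range = 255))

setValidity("FrameStack", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3D array [row, col, frame]")
  if (object@fps <= 0) return("fps must be positive")
  if (object@range <= 0) return("range must be positive")
  TRUE
})

#' Keyframe annotations
#'
#' User-defined 2D marker positions at selected frames; the anchors of
#' bidirectional tracking propagation. Annotations are per frame, per
#' marker, per camera.
#'
#' @slot annotations named list: `annotations[[as.character(frame)]]` is a
#'   named list mapping marker name to a list of two numeric(2) pixel
#'   positions (one per camera; NA allowed for a camera with no click).
#' @export
setClass("KeyframeSet", representation(annotations = "list"))

setValidity("KeyframeSet", function(object) {
  if (length(object@annotations) &&
      (is.null(names(object@annotations)) ||
       anyNA(suppressWarnings(as.integer(names(object@annotations))))))
    return("annotations must be named by integer frame index")
  TRUE
})

#' Tracked marker state
#'
#' Per-frame, per-marker results of tracking: 3D position, the per-camera 2D
#' measurements, a provenance flag and the triangulation error. Status codes:
#' 0 = untracked, 1 = user-defined, 2 = tracked, 3 = reverted (lost; held at
#' the last accepted 3D position).
#'
#' @slot pos3d numeric array nframes x nmarkers x 3.
#' @slot pos2d numeric array nframes x nmarkers x 2 (camera) x 2 (u, v).
#' @slot status integer matrix nframes x nmarkers.
#' @slot triError numeric matrix nframes x nmarkers.
#' @slot markers character vector of marker names (column order).
#' @slot fps frame rate (Hz).
#' @export
setClass("TrackState",
  representation(pos3d = "array", pos2d = "array", status = "matrix",
                 triError = "matrix", markers = "character",
                 fps = "numeric"))

setValidity("TrackState", function(object) {
  d <- dim(object@pos3d)
  if (length(d) != 3L || d[3] != 3L)
    return("pos3d must be nframes x nmarkers x 3")
  if (!identical(dim(object@pos2d), c(d[1], d[2], 2L, 2L)))
    return("pos2d must be nframes x nmarkers x 2 x 2")
  if (!identical(dim(object@status), d[1:2]))
    return("status must be nframes x nmarkers")
  if (length(object@markers) != d[2])
    return("markers length must match pos3d")
  TRUE
})

#' Animal-centered body frame
#'
#' The rigid transform taking raw (calibration-jig) coordinates into the
#' canonical animal frame: x toward the head, y to the animal's left, z up
#' from the substrate, with the median foot (TiTa) plane at z = 0.
#' Application is `q = R p + translation`.
#'
#' @slot rotation 3x3 orthonormal, det +1.
#' @slot translation numeric(3).
#' @slot provenance list of summaries used to build the frame (per-leg
#'   median TiTa points, anchor means).
#' @export
setClass("BodyFrame",
  representation(rotation = "matrix", translation = "numeric",
                 provenance = "list"),
  prototype(rotation = diag(3), translation = c(0, 0, 0),
            provenance = list()))

setValidity("BodyFrame", function(object) {
  if (!.isOrthonormal(object@rotation))
    return("rotation must be orthonormal with det +1")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  TRUE
})

#' Stride timing model
#'
#' Trial-level stride parameters: per-leg spectral peak frequencies, their
#' mean f, the per-leg stance-cluster Gaussian parameters (mu, sigma) of the
#' foot height, and the transition search window width w = 1/(4 f) seconds.
#'
#' @slot legFreqs named numeric, per-leg peak frequency (Hz).
#' @slot f trial frequency (Hz), mean of per-leg peaks.
#' @slot mu named numeric, lower (stance) cluster mean of z per leg.
#' @slot sigma named numeric, lower cluster standard deviation per leg.
#' @slot w window width 1/(4 f) in seconds.
#' @export
setClass("StrideModel",
  representation(legFreqs = "numeric", f = "numeric", mu = "numeric",
                 sigma = "numeric", w = "numeric"))

setValidity("StrideModel", function(object) {
  if (length(object@f) != 1L || object@f <= 0) return("f must be positive")
  if (abs(object@w - 1 / (4 * object@f)) > 1e-12)
    return("w must equal 1/(4 f)")
  if (length(object@sigma) && any(object@sigma < 0))
    return("sigma must be non-negative")
  TRUE
})

#' Stride events
#'
#' Ordered swing/stance onset times per leg under each segmentation method
#' ("extrema" = anterior/posterior extreme positions; "zheight" = foot
#' height against the stance cluster).
#'
#' @slot events data.frame with columns `leg`, `method`, `type`
#'   ("swing"/"stance"), `time_s`, `inherited` (logical; a zheight event
#'   that fell back to the extrema time).
#' @export
setClass("StrideEvents", representation(events = "data.frame"))

setValidity("StrideEvents", function(object) {
  ev <- object@events
  need <- c("leg", "method", "type", "time_s", "inherited")
  if (!all(need %in% names(ev))) return("missing event columns")
  for (lg in unique(ev$leg)) for (m in unique(ev$method)) {
    e <- ev[ev$leg == lg & ev$method == m, ]
    if (nrow(e) > 1L) {
      if (any(diff(e$time_s) <= 0))
        return("event times must be strictly increasing per leg/method")
      if (any(e$type[-1] == e$type[-nrow(e)]))
        return("swing and stance onsets must alternate")
    }
  }
  TRUE
})

#' Programmed gait specification
#'
#' Ground-truth kinematics of the synthetic tethered hexapod. The tibia-
#' tarsus (foot) point follows a stance (linear backward at z = 0) / swing
#' (forward with sinusoidal lift) cycle; proximal joints follow through a
#' fixed-segment-length kinematic chain. Lengths in mm, times in seconds.
#'
#' @slot freq step frequency (Hz).
#' @slot duty duty cycle, fraction of the cycle in stance, in (0, 1).
#' @slot phases named numeric(6), per-leg phase offsets in [0, 1).
#' @slot strideLength foot excursion along x (mm).
#' @slot liftHeight swing apex height (mm).
#' @slot xLead fraction of cycle by which backward foot motion leads
#'   touchdown and trails liftoff (0 = extrema coincide with contact).
#' @slot coxaSwing amplitude (degrees) of the slow coxal rocking.
#' @slot geometry list of per-leg chain geometry (ThC position, coxa
#'   direction, segment lengths, neutral foot position); see
#'   [gaitSpec()] for the defaults.
#' @slot seed integer random seed governing all stochastic rendering.
#' @export
setClass("GaitSpec",
  representation(freq = "numeric", duty = "numeric", phases = "numeric",
                 strideLength = "numeric", liftHeight = "numeric",
                 xLead = "numeric", coxaSwing = "numeric",
                 geometry = "list", seed = "integer"))

setValidity("GaitSpec", function(object) {
  if (object@freq <= 0) return("freq must be positive")
  if (object@duty <= 0 || object@duty >= 1) return("duty must be in (0,1)")
  if (length(object@phases) != 6L || any(object@phases < 0) ||
      any(object@phases >= 1))
    return("phases must be six values in [0,1)")
  if (object@strideLength <= 0 || object@liftHeight <= 0)
    return("strideLength and liftHeight must be positive")
  if (object@xLead < 0 || object@xLead >= min(object@duty, 1 - object@duty) / 2)
    return("xLead must be small and non-negative")
  TRUE
})

#' Rendering specification for synthetic stereo video
#'
#' @slot imageSize integer(2), width x height in px (default 320 x 280).
#' @slot scalePxPerCm nominal working-volume scale (default 30 px/cm).
#' @slot blobSigma Gaussian marker blob sigma (px).
#' @slot blobPeak marker peak intensity (8-bit units).
#' @slot clutterAmp static background clutter amplitude as a fraction of
#'   blobPeak (low-frequency pattern; default 0.3).
#' @slot noiseSd additive i.i.d. sensor noise sd (8-bit units).
#' @slot occlusions data.frame scheduling transient marker dropouts:
#'   columns `marker`, `from`, `to` (frames, inclusive), `camera`
#'   (1, 2, or NA for both).
#' @slot fps frame rate (Hz, default 500).
#' @export
setClass("RenderSpec",
  representation(imageSize = "integer", scalePxPerCm = "numeric",
                 blobSigma = "numeric", blobPeak = "numeric",
                 clutterAmp = "numeric", noiseSd = "numeric",
                 occlusions = "data.frame", fps = "numeric"),
  prototype(imageSize = c(320L, 280L), scalePxPerCm = 30, blobSigma = 1.5,
            blobPeak = 220, clutterAmp = 0.3, noiseSd = 2,
            occlusions = data.frame(marker = character(), from = integer(),
                                    to = integer(), camera = integer()),
            fps = 500))

setValidity("RenderSpec", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    return("imageSize must be width x height, each >= 8 px")
  if (object@scalePxPerCm <= 0) return("scalePxPerCm must be positive")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@blobSigma <= 0) return("blobSigma must be positive")
  TRUE
})
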