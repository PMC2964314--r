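#' @rdname CameraModel-class
#' @param object,x an object.
#' @export
setGeneric("focal", function(object) standardGeneric("focal"))

#' @rdname CameraModel-class
#' @export
setGeneric("principal", function(object) standardGeneric("principal"))

#' @rdname CameraModel-class
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))

#' @rdname CameraModel-class
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))

#' @rdname CameraModel-class
#' @export
setGeneric("cameraCenter", function(object) standardGeneric("cameraCenter"))

#' @rdname MarkerTopology-class
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname MarkerTopology-class
#' @export
setGeneric("legs", function(object) standardGeneric("legs"))

#' @rdname MarkerTopology-class
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' Number of frames in an object with a time axis
#' @param object a [FrameStack-class] or [TrackState-class].
#' @return integer(1).
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @param object,i frame stack and frame index.
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))

#' @rdname TrackState-class
#' @export
setGeneric("positions3d", function(object) standardGeneric("positions3d"))

#' @rdname TrackState-class
#' @export
setGeneric("positions2d", function(object) standardGeneric("positions2d"))

#' @rdname TrackState-class
#' @export
setGeneric("trackStatus", function(object) standardGeneric("trackStatus"))

#' @rdname TrackState-class
#' @export
setGeneric("triangulationErrors",
           function(object) standardGeneric("triangulationErrors"))

#' Count the 3D estimates held by a track
#'
#' The bookkeeping size of a tracked bout: one 3D estimate per frame per
#' marker that carries a position (user, tracked or reverted), and two 2D
#' image points per 3D estimate (one per camera).
#'
#' @param object a [TrackState-class].
#' @return `nEstimates3d`: integer count of 3D positions;
#'   `nPoints2d`: integer count of underlying 2D points.
#' @export
setGeneric("nEstimates3d", function(object) standardGeneric("nEstimates3d"))

#' @rdname nEstimates3d
#' @export
setGeneric("nPoints2d", function(object) standardGeneric("nPoints2d"))

#' Keyframe accessors
#' @param object a [KeyframeSet-class].
#' @return `keyframeIndices`: sorted integer frame indices.
#' @export
setGeneric("keyframeIndices",
           function(object) standardGeneric("keyframeIndices"))
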