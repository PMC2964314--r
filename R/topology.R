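#' The standard 26-marker hexapod topology
#'
#' Six legs named `R1, L1, R2, L2, R3, L3` (right/left front, middle, hind;
#' leg 1 is the right front). Each leg is the proximal-to-distal chain
#' `ThC -> CTr -> FTi -> TiTa` (thorax-coxa, coxa-trochanter, femur-tibia,
#' tibia-tarsus); the front legs carry one additional coxal marker (`Cx`,
#' depth 1, proximal neighbour ThC) midway along the coxa, used to resolve
#' the coxal long-axis rotation. Marker names are `<leg>.<joint>`, e.g.
#' `"R2.TiTa"`.
#'
#' @return a [MarkerTopology-class] with 26 markers.
#' @examples
#' topo <- hexapodTopology()
#' nMarkers(topo)   # 26
#' @export
hexapodTopology <- function() {
  legs <- c("R1", "L1", "R2", "L2", "R3", "L3")
  pair <- c(R1 = "front", L1 = "front", R2 = "middle", L2 = "middle",
            R3 = "hind", L3 = "hind")
  rows <- list()
  for (lg in legs) {
    side <- substr(lg, 1L, 1L)
    chain <- data.frame(
      marker = paste(lg, c("ThC", "CTr", "FTi", "TiTa"), sep = "."),
      leg = lg, side = side, pair = pair[[lg]],
      joint = c("ThC", "CTr", "FTi", "TiTa"),
      depth = 0:3,
      proximal = c(NA, paste(lg, c("ThC", "CTr", "FTi"), sep = ".")),
      stringsAsFactors = FALSE)
    rows[[lg]] <- chain
    if (pair[[lg]] == "front") {
      rows[[paste0(lg, ".cx")]] <- data.frame(
        marker = paste0(lg, ".Cx"), leg = lg, side = side, pair = "front",
        joint = "Cx", depth = 1L, proximal = paste0(lg, ".ThC"),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new("MarkerTopology", markers = df)
}

#' @rdname MarkerTopology-class
#' @export
setMethod("markers", "MarkerTopology", function(object)
  object@markers$marker)

#' @rdname MarkerTopology-class
#' @export
setMethod("legs", "MarkerTopology", function(object)
  unique(object@markers$leg))

#' @rdname MarkerTopology-class
#' @export
setMethod("nMarkers", "MarkerTopology", function(object)
  nrow(object@markers))

setMethod("show", "MarkerTopology", function(object) {
  df <- object@markers
  cat(sprintf("MarkerTopology: %d markers on %d legs\n",
              nrow(df), length(unique(df$leg))))
  for (lg in unique(df$leg)) {
    sub <- df[df$leg == lg, ]
    cat(sprintf("  %s: %s\n", lg,
                paste(sub$joint[order(sub$depth, sub$joint)],
                      collapse = " -> ")))
  }
  invisible(object)
})

# ordered marker rows for one leg, proximal before distal (ties by name so
# the front-leg coxal marker precedes CTr deterministically)
.legOrder <- function(topology, leg) {
  sub <- topology@markers[topology@markers$leg == leg, ]
  sub[order(sub$depth, sub$joint), ]
}

.markerRow <- function(topology, marker) {
  i <- match(marker, topology@markers$marker)
  if (is.na(i)) stop("unknown marker: ", marker)
  topology@markers[i, ]
}
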