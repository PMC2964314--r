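# HexaTrack run configuration (annotated defaults)
#
# All lengths are in world units (mm for the reference rig at 30 px/cm);
# pixel quantities are in pixels. Remove a key to keep its default.

paths:
  movie1: camera1.tiff        # camera 1 multi-page TIFF (or frame dir)
  movie2: camera2.tiff        # camera 2 movie
  cameras: [camera1.yaml, camera2.yaml]
  keyframes: keyframes.json   # user annotations (frame -> marker -> uv)
  out: results                # output directory

filter:
  nBackgroundFrames: 100      # frames averaged into the background image
  backgroundSigma: 5          # Gaussian sigma (px) before averaging
  medianWidth: 5              # median filter width (px, odd)

tracker:
  baseRadius: 1.0             # ellipsoid long radius r0 at depth 1 (mm)
  depthScale: 1.3             # exponential per-depth scale g (> 1)
  thcRadius: 0.5              # ThC search sphere radius (mm)
  enlargeFactor: 2            # radius multiplier on a dim centroid
  maxEnlarge: 2               # maximum enlargement retries per camera
  triErrorMax: 1.0            # triangulation-error gate (mm)
  segLenFactor: 1.3           # segment length-change gate (ratio)
  dimFraction: 0.5            # dim threshold vs frame median brightness
  dimFloor: 1                 # absolute brightness floor (8-bit units)

strides:
  band: [0.5, 15]             # spectral peak search band (Hz)

seed: 1                       # seed recorded in the run manifest
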