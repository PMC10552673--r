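# Annotated musclehisto pipeline configuration.
#
# Any field left out falls back to the package default for the selected
# assay (see default_pipeline_config()). Sizes and diameters are pixels;
# intensities and thresholds live on [0, 1].

# Which pipeline to run: ebd | emyhc | cd68 | collagen
assay: ebd

# Which image channel carries which biological role. Staining conventions
# differ between assays: the EBD damage assay uses laminin=green, ebd=red;
# the eMyHC and CD68 assays use laminin=red, marker=green; the collagen
# assay reads collagen from the green plane of the brightfield image.
channel_roles:
  laminin: green
  ebd: red

# Exponent of the dye-masking power transform (EBD assay only). 2 squares
# the combined inverted gray image so dye-filled fibers drop out of the
# "not-EBD" identification pass.
square_exponent: 2

# Fiber-scale identification (EBD and eMyHC assays).
cell_params:
  min_diameter: 10        # inclusive bounds on the area-equivalent
  max_diameter: 150       #   diameter 2*sqrt(area/pi), in pixels
  declump: true           # split touching fibers by shape
  smoothing_sigma: 6      # Gaussian sigma for the distance-map smoothing;
                          #   raise if fibers are over-segmented, lower if
                          #   under-segmented. "auto" = min_diameter/4
  min_seed_distance: 12   # minimum seed separation; "auto" = min_diameter/2
  fill_holes: true
  discard_border: false   # edge-clipped fibers are counted by default
  threshold:
    method: robust_background
    n_sd: 2               # threshold = trimmed mean + n_sd * sd
    trim_low: 0.05        # dimmest fraction removed before the statistics
    trim_high: 0.05       # brightest fraction removed (doubles as the
                          #   foreground-removal step)
    lower_bound: 0.0      # clamp applied to the selected threshold; raise
    upper_bound: 0.8      #   or lower these when automatic selection fails
                          #   on an atypical frame

# Marker-scale identification (eMyHC, CD68 and collagen assays). Unused by
# the EBD assay; shown here with the CD68/collagen defaults.
marker_params:
  min_diameter: 10
  max_diameter: 200
  declump: false
  fill_holes: true
  threshold:
    method: min_cross_entropy
    bins: 256             # candidate thresholds are the bin edges k/bins
    lower_bound: 0.1      # floor: pure-noise frames yield no foreground
    upper_bound: 1.0
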