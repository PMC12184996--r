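# Example analysis configuration. Any key omitted here keeps its package
# default (see ?default_config). Units: seconds for durations, pixels for
# the live-mode fallbacks; thresholds on the activity index are unitless.
fps: 30
cleaning:
  likelihood_threshold: 0.6
  max_gap_frames: 5
landmark_aliases:
  LeftEar: ear_left
  RightEar: ear_right
metrics:
  window_s: 2.0
  blink_max_s: 1.0
  closure_fraction: 0.4
scoring:
  weights:
    EAR_LEFT: 1
    EAR_RIGHT: 0      # e.g. an ear obscured by the head-post
    EYE_LEFT: 1
    EYE_RIGHT: 1
    NOSE: 1
live:
  baseline_window_s: 60
  hysteresis_frames: 15
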