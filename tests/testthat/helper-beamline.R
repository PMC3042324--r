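# Shared desk-scale fixtures: detectors keep the 1.5 mm field of view of the
# reference microscope but at reduced pixel counts so tests stay fast.

clean_det <- function(n = 128) {
  detector_config(n, n, 1500 / n, 1500 / n,
                  noise_sigma = 0, fringe_amplitude = 0, fringe_width_px = 0)
}

study_det <- function(n = 512) {
  detector_config(n, n, 1500 / n, 1500 / n,
                  noise_sigma = 0.02, fringe_amplitude = 0.5,
                  fringe_width_px = if (n >= 512) 4 else 2)
}

femur_phantom <- function(...) phantom_sample(...)

# a narrow cylinder whose silhouette stays inside the field of view even when
# offset and tilted; ideal for exact parameter-recovery checks. Absorption is
# raised so the thin rod still sits well above the segmentation threshold
# (a 0.1 mm radius at the default 1.5/mm would peak exactly at 0.3).
slim_phantom <- function(radius = 0.1, length = 12, mu_sample = 4, ...) {
  phantom_sample(length = length, radius_x = radius, radius_z = radius,
                 mu_sample = mu_sample, ...)
}

# stage viewing mid-specimen (the nominal load height)
mid_stage <- function(sample, ...) {
  stage_state(y = -sample$length * 1000 / 2, ...)
}
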