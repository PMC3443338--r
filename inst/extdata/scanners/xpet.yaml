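# BGO block scanner preset (X-PET class). Lengths in mm, energies in keV,
# times in ns; energy_resolution is the FWHM fraction at 511 keV.
# coincidence_window_ns and timing_resolution_ns are documented
# assumptions (not part of the published specification).
name: X-PET
ring_inner_diameter_mm: 165.0
crystals_per_ring: 240
n_rings: 48
axial_fov_mm: 116.0
crystal_depth_mm: 9.4
energy_resolution: 0.25
let_kev: 250.0
uet_kev: 750.0
coincidence_window_ns: 12.0
timing_resolution_ns: 3.0
crystal_mu_511_cm: 0.95
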