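# LYSO/LGSO phoswich scanner preset (LabPET-8 class). Lengths in mm,
# energies in keV, times in ns. The phoswich distinction is not modeled:
# a single energy response and coincidence window stand for both members.
name: LabPET-8
ring_inner_diameter_mm: 162.0
crystals_per_ring: 192
n_rings: 32
axial_fov_mm: 75.0
crystal_depth_mm: 14.0
energy_resolution: 0.25
let_kev: 250.0
uet_kev: 650.0
coincidence_window_ns: 20.0
timing_resolution_ns: 9.0
crystal_mu_511_cm: 0.87
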