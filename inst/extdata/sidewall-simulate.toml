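# Idealized sidewall aneurysm, coiled to 30% packing density.
# Lengths in mm, velocities in m/s.

[geometry]
configuration = "sidewall"
vessel_diameter = 4
dome_diameter = 8
neck_width = 4
inlet_length = 8
outlet_length = 8
slab_depth = 1
h = 0.4

[coil]
packing_density = 30
D_P_inches = 0.010

[fluid]
rho = 1056
mu = 0.0035

[boundary]
inlet_mean_velocity = 0.25
waveform = "constant"
period = 0.9
profile = "parabolic"

[solver]
steady_tolerance = 1e-5
time_step = 1e-4
n_cycles = 2
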