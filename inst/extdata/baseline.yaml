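# Reference setup: symbiotic variant, evenly mixed initial condition
# under the sinusoidal interface, 200 x 200 grid, time step 1/200 day,
# batch (no-flow) acid boundary. Dimensional entries in SI units.
parameters:
  W: 3.0e-4
  H: 3.0e-4
  s1_bar: 10.0
  D1: 5.0e-10
  D2: 1.0e-9
  rho_s: 1100.0
  rho_v: 1100.0
  Y_s1: 0.1
  Y_v1: 0.1
  Y_v2: 0.1
  lam: 0.5
  mu1: 3.0e-5
  mu2: 8.0e-5
  k11: 0.878
  k21: 0.878
  k22: 0.0878
  kl: 1.0
  t_d: 86400.0
grid:
  nx: 200
  nz: 200
solver:
  dT: 0.005
  T_end: 2.0
  acid_bc: noflow
initial:
  variant: mixed
  mean: 0.1
  amplitude: 0.05
  wavenumber: 12.566370614359172
  phase: 1.5707963267948966
  frac1: 0.5
variant: symbiotic
seed: 1
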