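# Default parameterization of the LGN network model.
# Izhikevich parameters per population (tonic-firing RS/FS presets), synaptic
# projection attributes (connection probability, weight in nA, delay in ms),
# synapse kinetics and the analysis-chain settings.  Any field may be
# overridden through a user configuration file (see load_config()).
kinetics:
  tau_e: 2.0    # ms, excitatory current decay
  tau_i: 6.0    # ms, inhibitory current decay
populations:
  TCR: {size: 80, spiking: RS, a: 0.02, b: 0.2, c: -65, d: 6, v_init: -65, u_init: -13, i_dc: 0}
  IN:  {size: 20, spiking: FS, a: 0.1,  b: 0.2, c: -65, d: 6, v_init: -70, u_init: -14, i_dc: 0}
  TRN: {size: 40, spiking: RS, a: 0.02, b: 0.2, c: -65, d: 6, v_init: -75, u_init: -15, i_dc: 0}
  RET: {size: 144}   # retinal spike-source channels (12 x 12), not Izhikevich cells
projections:
  - {pre: TCR, post: TRN, p_conn: 0.35,  w_syn: 3, d_conn: 8,  sign: excitatory}
  - {pre: IN,  post: TCR, p_conn: 0.232, w_syn: 8, d_conn: 6,  sign: inhibitory}
  - {pre: IN,  post: IN,  p_conn: 0.236, w_syn: 2, d_conn: 4,  sign: inhibitory}
  - {pre: TRN, post: TCR, p_conn: 0.077, w_syn: 2, d_conn: 8,  sign: inhibitory}
  - {pre: TRN, post: TRN, p_conn: 0.20,  w_syn: 2, d_conn: 4,  sign: inhibitory}
  - {pre: RET, post: TCR, p_conn: 0.071, w_syn: 5, d_conn: 10, sign: excitatory}
  - {pre: RET, post: IN,  p_conn: 0.474, w_syn: 4, d_conn: 10, sign: excitatory}
variants:
  # Feed-forward inhibition (IN -> TCR) suppressed, feedback inhibition
  # (TRN -> TCR) made dominant.
  in_suppressed:
    - {pre: IN,  post: TCR, p_conn: 0.07,  w_syn: 1}
    - {pre: TRN, post: TCR, p_conn: 0.309}
simulation:
  duration: 6000   # ms
  dt: 0.1          # ms
  n_trials: 10
analysis:
  epoch: [500, 5500]   # ms, analyzed window of the averaged series
  fs_out: 1000         # Hz, downsampled rate
  band: [1, 100]       # Hz, Butterworth bandpass corners
  order: 10            # Butterworth prototype order
  seg_len: 1000        # Welch segment length, samples
  overlap: 0.5         # Welch segment overlap fraction
  pad_factor: 4        # zero-padding factor of the Welch transform length
dvs:
  K: 1.0          # log-conversion constant, V per ln-unit
  A: 5.0          # differentiator gain
  V_ref: 0.0      # reset reference, V
  V_t_plus: 1.0   # ON threshold, V
  V_t_minus: -1.0 # OFF threshold, V
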