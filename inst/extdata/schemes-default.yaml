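# Default activity-partition schemes ("reference mode").
#
# Single-metric schemes bin one activity descriptor with left-closed,
# right-open intervals; edges in the metric's units. Spike-frequency and
# duty-cycle edges follow the published segmentation of this database family;
# rise-phase-slope edges are config choices (the source chose them by eye
# from population histograms and reports robustness to boundary shifts).
#
# Pacemaker criteria are closed ranges combined by conjunction. The
# slow-wave-amplitude range (10-30 mV) is fixed by the analysis this package
# implements; the remaining ranges are transcribed approximations of the
# published STG pacemaker-kernel criteria and are config entries.
schema_version: 1
name: reference
single_metric:
  spike_frequency:        # Hz, periodic spikers
    class: periodic_spiking
    edges: [10, 25, 50, 75]
  duty_cycle:             # dimensionless, periodic bursters
    class: periodic_bursting
    edges: [0.05, 0.1, 0.2, 0.4, 0.6]
  slope_average:          # mV/ms, periodic bursters
    class: periodic_bursting
    edges: [0.01, 0.02, 0.04, 0.08]
  slope_initial:          # mV/ms, off-centre variant (status: config choice)
    class: periodic_bursting
    edges: [0.005, 0.01, 0.02, 0.04]
  slope_central:          # mV/ms
    class: periodic_bursting
    edges: [0.025, 0.05, 0.1, 0.2]
  # Implemented but disabled by default: lower overall correlation yield.
  spike_height:
    class: periodic_spiking
    edges: [20, 40, 60]
    enabled: false
  spikes_per_burst:
    class: periodic_bursting
    edges: [2, 4, 8, 16]
    enabled: false
pacemaker_criteria:       # closed ranges, conjunction; status: transcribed approximation
  slow_wave_amplitude: [10.0, 30.0]     # mV (fixed by the analysis)
  slow_wave_peak: [-45.0, -20.0]        # mV
  duty_cycle: [0.2, 0.5]
  burst_period: [1000.0, 2000.0]        # ms
  spikes_per_burst: [4.0, 30.0]
correlation:
  chi2_cutoff: 500        # raw statistic, strict inequality
  rho_cutoff: 0.2         # |rho|, strict inequality
  mask_threshold: 0.03    # fraction of type_i models per grid cell, inclusive
  low_n_warn: 1000        # population size below which scan warns
  edge_flag_fraction: 0.5 # mass in level-0 row/column that flags a result
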