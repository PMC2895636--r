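# Channel kinetics and membrane configuration for the single-compartment
# STG-style model neuron (8 currents + intracellular calcium pool).
#
# Transcribed from the published model-database lineage (Prinz, Billimoria &
# Marder 2003, J Neurophysiol 90:3998-4015; kinetics after Liu et al. 1998,
# Turrigiano et al. 1995; H current after Huguenard & McCormick 1992).
# Status "transcribed": values copied from those published tables, not fit here.
#
# Functional forms (V in mV, Ca in uM, tau in ms):
#   logistic:     1 / (1 + exp((V - vhalf) / k))
#   logistic_ca:  Ca / (Ca + ca_half) * 1 / (1 + exp((V - vhalf) / k))
#   constant:     a
#   sigmoid:      a + b / (1 + exp((V - vhalf) / k))
#   biexp:        a + b / (exp((V - vhalf1) / k1) + exp((V - vhalf2) / k2))
#   prodsig:      s / (1 + exp((V - vhalf1) / k1)) * (c + 1 / (1 + exp((V - vhalf2) / k2)))
#
# Each ionic current is I = gbar * m^p * h^q * (V - E), gbar in mS/cm^2,
# I as a density in uA/cm^2. reversal: mV, or "calcium" for the Nernst-dynamic
# calcium reversal recomputed from the intracellular concentration each step.
schema_version: 1
name: stg-prinz2003
status: transcribed
membrane:
  capacitance: 1.0        # uF/cm^2 (0.628 nF over 0.628e-3 cm^2)
  area: 0.000628          # cm^2
  v_range: [-120.0, 60.0] # mV; kinetics tables clamped outside this range
calcium:
  tau: 200.0              # ms, buffering time constant
  f: 14.96                # uM/nA, calcium-current-to-concentration factor
  rest: 0.05              # uM, steady-state concentration with no Ca current
  external: 3000.0        # uM, fixed extracellular concentration
  nernst_prefactor: 12.2  # mV, RT/2F with natural log
channels:
  - name: Na
    reversal: 50.0
    p: 3
    q: 1
    m_inf: {form: logistic, vhalf: -25.5, k: -5.29}
    tau_m: {form: sigmoid, a: 1.32, b: -1.26, vhalf: -120.0, k: -25.0}
    h_inf: {form: logistic, vhalf: -48.9, k: 5.18}
    tau_h: {form: prodsig, s: 0.67, vhalf1: -62.9, k1: -10.0, c: 1.5, vhalf2: -34.9, k2: 3.6}
  - name: CaT
    reversal: calcium
    p: 3
    q: 1
    m_inf: {form: logistic, vhalf: -27.1, k: -7.2}
    tau_m: {form: sigmoid, a: 43.4, b: -42.6, vhalf: -68.1, k: -20.5}
    h_inf: {form: logistic, vhalf: -32.1, k: 5.5}
    tau_h: {form: sigmoid, a: 210.0, b: -179.6, vhalf: -55.0, k: -16.9}
  - name: CaS
    reversal: calcium
    p: 3
    q: 1
    m_inf: {form: logistic, vhalf: -33.0, k: -8.1}
    tau_m: {form: biexp, a: 2.8, b: 14.0, vhalf1: -27.0, k1: 10.0, vhalf2: -70.0, k2: -13.0}
    h_inf: {form: logistic, vhalf: -60.0, k: 6.2}
    tau_h: {form: biexp, a: 120.0, b: 300.0, vhalf1: -55.0, k1: 9.0, vhalf2: -65.0, k2: -16.0}
  - name: A
    reversal: -80.0
    p: 3
    q: 1
    m_inf: {form: logistic, vhalf: -27.2, k: -8.7}
    tau_m: {form: sigmoid, a: 23.2, b: -20.8, vhalf: -32.9, k: -15.2}
    h_inf: {form: logistic, vhalf: -56.9, k: 4.9}
    tau_h: {form: sigmoid, a: 77.2, b: -58.4, vhalf: -38.9, k: -26.5}
  - name: KCa
    reversal: -80.0
    p: 4
    q: 0
    m_inf: {form: logistic_ca, vhalf: -28.3, k: -12.6, ca_half: 3.0}
    tau_m: {form: sigmoid, a: 180.6, b: -150.2, vhalf: -46.0, k: -22.7}
  - name: Kd
    reversal: -80.0
    p: 4
    q: 0
    m_inf: {form: logistic, vhalf: -12.3, k: -11.8}
    tau_m: {form: sigmoid, a: 14.4, b: -12.8, vhalf: -28.3, k: -19.2}
  - name: H
    reversal: -20.0
    p: 1
    q: 0
    m_inf: {form: logistic, vhalf: -75.0, k: 5.5}
    tau_m: {form: biexp, a: 0.0, b: 2.0, vhalf1: -169.7, k1: -11.6, vhalf2: 26.7, k2: 14.3}
  - name: leak
    reversal: -50.0
    p: 0
    q: 0
# Grid of maximal conductance levels (mS/cm^2) used to build the full
# 6^8-model database; each conductance varied independently over these
# equidistant values from zero to a physiologically plausible maximum.
grid:
  Na:   [0.0, 100.0, 200.0, 300.0, 400.0, 500.0]
  CaT:  [0.0, 2.5, 5.0, 7.5, 10.0, 12.5]
  CaS:  [0.0, 2.0, 4.0, 6.0, 8.0, 10.0]
  A:    [0.0, 10.0, 20.0, 30.0, 40.0, 50.0]
  KCa:  [0.0, 5.0, 10.0, 15.0, 20.0, 25.0]
  Kd:   [0.0, 25.0, 50.0, 75.0, 100.0, 125.0]
  H:    [0.0, 0.01, 0.02, 0.03, 0.04, 0.05]
  leak: [0.0, 0.01, 0.02, 0.03, 0.04, 0.05]
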