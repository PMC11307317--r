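# Resilience scenario: the generalist inoculated 100-fold lower at
# passage 1.  Fast re-adapter: reference kinetics recovered at the
# second passage.
scenario: resilience_bt
base: consortium
dilution:
  B_thetaiotaomicron: 0.01
adaptation:
  lag_excess: {B_thetaiotaomicron: 0.01}
  mu_deficit: 0.0
  factor: 0.2
truth:
  recovery_passage: 2
  composition:
    A_muciniphila: 0.343
    B_thetaiotaomicron: 0.525
    F_prausnitzii: 0.131
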