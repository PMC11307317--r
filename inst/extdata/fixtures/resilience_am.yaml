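# Resilience scenario: the mucin specialist inoculated 100-fold lower at
# passage 1.  The under-inoculated strain re-adapts over passages (lag
# excess decaying geometrically); its kinetic offset crosses the
# reference detection threshold at the designed recovery passage.
scenario: resilience_am
base: consortium
dilution:
  A_muciniphila: 0.01
adaptation:
  lag_excess: {A_muciniphila: 1.16}
  mu_deficit: 0.0
  factor: 0.35
truth:
  recovery_passage: 5
  composition:
    A_muciniphila: 0.343
    B_thetaiotaomicron: 0.525
    F_prausnitzii: 0.131
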