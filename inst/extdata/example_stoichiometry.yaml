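# Stoichiometry hypotheses for the reconstituted RNP particles.
# Component sequences: synthetic_rnp_components.fasta (synthetic stand-ins
# sized to the documented component masses).
kinds:
  synthetic_snR51: rna
  synthetic_sR26: rna
models:
  snR51_RNP_1xSnu13:
    synthetic_Nop5: 2
    synthetic_Fib: 2
    synthetic_Snu13: 1
    synthetic_snR51: 1
  sR26_RNP_1xSnu13:
    synthetic_Nop5: 2
    synthetic_Fib: 2
    synthetic_Snu13: 1
    synthetic_sR26: 1
  sR26_RNP_2xSnu13:
    synthetic_Nop5: 2
    synthetic_Fib: 2
    synthetic_Snu13: 2
    synthetic_sR26: 1
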