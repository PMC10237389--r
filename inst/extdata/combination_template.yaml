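# Template for a multi-protocol "combination" experiment: one file per
# protocol, loaded with read_protocol() and combined with
# count_independent_points(list(...)). The stimulus shapes below follow the
# published pulse patterns; fill in the measurement schedules (minutes) for
# each genotype and observable to reproduce a specific experimental design.
# Observables: IKKa, NFkBn, IkBa_total, A20 (WT only), IkBat.
name: pulses_3x5min_gap200min_template
segments:
- [0, 5, 1]
- [5, 205, 0]
- [205, 210, 1]
- [210, 410, 0]
- [410, 415, 1]
- [415, 720, 0]
schedule:
  WT:
    IKKa: []
    NFkBn: []
    IkBa_total: []
    A20: []
    IkBat: []
  A20KO:
    IKKa: []
    NFkBn: []
    IkBa_total: []
    IkBat: []
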