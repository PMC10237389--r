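name: on_off
segments:
- - 0.0
  - 120.0
  - 1.0
- - 120.0
  - 720.0
  - 0.0
schedule:
  WT:
    IKKa:
    - 0.0
    - 5.0
    - 30.0
    NFkBn:
    - 0.0
    - 5.0
    - 30.0
    - 60.0
    - 90.0
    - 120.0
    - 150.0
    - 180.0
    IkBa_total:
    - 0.0
    - 5.0
    - 30.0
    - 60.0
    - 120.0
    - 180.0
    - 300.0
    - 720.0
    A20:
    - 0.0
    - 30.0
    - 60.0
    - 300.0
    IkBat:
    - 0.0
    - 30.0
    - 60.0
    - 300.0
  A20KO:
    IKKa:
    - 0.0
    - 5.0
    - 30.0
    NFkBn:
    - 0.0
    - 5.0
    - 30.0
    - 60.0
    - 90.0
    - 120.0
    - 150.0
    - 180.0
    IkBa_total:
    - 0.0
    - 5.0
    - 30.0
    - 60.0
    - 120.0
    - 180.0
    - 300.0
    - 720.0
    IkBat:
    - 0.0
    - 30.0
    - 60.0
    - 300.0
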