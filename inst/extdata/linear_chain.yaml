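# Minimal three-compound transfer chain used in examples and tests.
# A is the tracer source: 40% of the pool labeled at carbons 1 and 2.
compounds:
  A: 3
  B: 3
  C: 3
reactions:
  - id: ab
    product: B
    substrates:
      - {compound: A, atoms: [1, 2, 3], to: [1, 2, 3]}
  - id: bc
    product: C
    substrates:
      - {compound: B, atoms: [1, 2, 3], to: [1, 2, 3]}
sources:
  A:
    labeled_positions: [1, 2]
    fraction: 0.4
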