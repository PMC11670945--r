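# Example strategy-definition config for read_strategy_config().
# Synthetic rule tables written for this package's documentation and
# tests; they are not parameter sets of any published strategy.
strategies:
  - name: Example Memory One
    type: memory_one
    vector: [0.9, 0.1, 0.8, 0.2]
    initial: C
  - name: Example FSM Grudge
    type: fsm
    initial_state: calm
    initial_action: C
    transitions:
      - {state: calm, input: C, next_state: calm, action: C}
      - {state: calm, input: D, next_state: angry, action: D}
      - {state: angry, input: C, next_state: angry, action: D}
      - {state: angry, input: D, next_state: angry, action: D}
  - name: Example Lookup TFT
    type: lookup
    depth: 1
    opening: [C]
    table:
      "C|C": C
      "C|D": D
      "D|C": C
      "D|D": D
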