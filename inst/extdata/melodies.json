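{
  "comment": "Default familiar melody table. Per-note totals across the four melodies (E=6, F=6, A=6, C=7) are normative for the design; the per-melody split is a package assumption because only the totals are unambiguous. Durations in seconds at 200 bpm.",
  "melodies": [
    {"melody_id": "Momiji",        "duration_s": 19.2, "note_counts": {"E": 2, "F": 2, "A": 2, "C": 2}},
    {"melody_id": "Harugakita",    "duration_s": 9.6,  "note_counts": {"E": 2, "F": 2, "A": 2, "C": 2}},
    {"melody_id": "Harunoogawa",   "duration_s": 19.2, "note_counts": {"E": 1, "F": 1, "A": 1, "C": 2}},
    {"melody_id": "Yuuyakekoyake", "duration_s": 19.2, "note_counts": {"E": 1, "F": 1, "A": 1, "C": 1}}
  ]
}
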