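{
  "home": [0, 0],
  "training_landmarks": [[0, 6], [-5.196152422706632, -3], [5.196152422706632, -3]],
  "test_landmarks": [[0, 6], [-5.196152422706632, -3], [5.196152422706632, -3]],
  "label": "L3"
}
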