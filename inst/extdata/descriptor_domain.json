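{
  "version": "1",
  "note": "Descriptor-space domain of the LLNA training/test partitions: per-descriptor minima and maxima.",
  "descriptors": {
    "NN":      {"train_min": 0,    "train_max": 5,    "test_min": 0,     "test_max": 8},
    "GNar":    {"train_min": 1.3,  "train_max": 2.3,  "test_min": 1.0,   "test_max": 2.9},
    "X2v":     {"train_min": 0,    "train_max": 9.97, "test_min": 0.27,  "test_max": 10.0},
    "EEig10r": {"train_min": -1.0, "train_max": 2.85, "test_min": -1.01, "test_max": 1.74},
    "GGI8":    {"train_min": 0.0,  "train_max": 0.95, "test_min": 0.0,   "test_max": 0.198},
    "nCconj":  {"train_min": 0,    "train_max": 6,    "test_min": 0,     "test_max": 6},
    "O-058":   {"train_min": 0,    "train_max": 6,    "test_min": 0,     "test_max": 3},
    "Me":      {"train_min": 0.96, "train_max": 1.15, "test_min": 0.96,  "test_max": 1.1},
    "PW2":     {"train_min": 0.4,  "train_max": 0.7,  "test_min": 0.0,   "test_max": 0.7},
    "PW3":     {"train_min": 0.0,  "train_max": 0.44, "test_min": 0.0,   "test_max": 0.37},
    "PCR":     {"train_min": 1.0,  "train_max": 1.7,  "test_min": 1.0,   "test_max": 1.53},
    "X3Av":    {"train_min": 0.0,  "train_max": 0.52, "test_min": 0.0,   "test_max": 0.36},
    "AAC":     {"train_min": 0.88, "train_max": 2.10, "test_min": 1.05,  "test_max": 2.25},
    "IVDE":    {"train_min": 0.0,  "train_max": 1.9,  "test_min": 0.0,   "test_max": 1.84}
  }
}
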