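{
  "electrodes": ["Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10"],
  "x": [-0.31, 0.31, -0.81, -0.42, 0, 0.42, 0.81, -0.67, -0.22, 0.22, 0.67, -1, -0.5, 0, 0.5, 1, -1.05, -0.67, -0.22, 0.22, 0.67, 1.05, -0.81, -0.42, 0, 0.42, 0.81, -0.63, -0.31, 0, 0.31, 0.63],
  "y": [0.95, 0.95, 0.59, 0.58, 0.55, 0.58, 0.59, 0.31, 0.28, 0.28, 0.31, 0, 0, 0, 0, 0, -0.35, -0.31, -0.28, -0.28, -0.31, -0.35, -0.59, -0.58, -0.55, -0.58, -0.59, -0.82, -0.95, -1, -0.95, -0.82],
  "neighbors": {
    "Fp1": ["F3", "Fz"],
    "Fp2": ["Fz", "F4"],
    "F7": ["F3", "FC5"],
    "F3": ["Fp1", "F7", "Fz", "FC5", "FC1"],
    "Fz": ["Fp1", "Fp2", "F3", "F4", "FC1", "FC2", "Cz"],
    "F4": ["Fp2", "Fz", "F8", "FC2", "FC6"],
    "F8": ["F4", "FC6"],
    "FC5": ["F7", "F3", "FC1", "T7", "C3"],
    "FC1": ["F3", "Fz", "FC5", "FC2", "C3", "Cz"],
    "FC2": ["Fz", "F4", "FC1", "FC6", "Cz", "C4"],
    "FC6": ["F4", "F8", "FC2", "C4", "T8"],
    "T7": ["FC5", "C3", "TP9", "CP5"],
    "C3": ["FC5", "FC1", "T7", "Cz", "CP5", "CP1"],
    "Cz": ["Fz", "FC1", "FC2", "C3", "C4", "CP1", "CP2", "Pz"],
    "C4": ["FC2", "FC6", "Cz", "T8", "CP2", "CP6"],
    "T8": ["FC6", "C4", "CP6", "TP10"],
    "TP9": ["T7", "CP5", "P7"],
    "CP5": ["T7", "C3", "TP9", "CP1", "P7", "P3", "PO9"],
    "CP1": ["C3", "Cz", "CP5", "CP2", "P3", "Pz"],
    "CP2": ["Cz", "C4", "CP1", "CP6", "Pz", "P4"],
    "CP6": ["C4", "T8", "CP2", "TP10", "P4", "P8", "PO10"],
    "TP10": ["T8", "CP6", "P8"],
    "P7": ["TP9", "CP5", "P3", "PO9"],
    "P3": ["CP5", "CP1", "P7", "Pz", "PO9", "O1"],
    "Pz": ["Cz", "CP1", "CP2", "P3", "P4", "O1", "Oz", "O2"],
    "P4": ["CP2", "CP6", "Pz", "P8", "O2", "PO10"],
    "P8": ["CP6", "TP10", "P4", "PO10"],
    "PO9": ["CP5", "P7", "P3", "O1"],
    "O1": ["P3", "Pz", "PO9", "Oz"],
    "Oz": ["Pz", "O1", "O2"],
    "O2": ["Pz", "P4", "Oz", "PO10"],
    "PO10": ["CP6", "P4", "P8", "O2"]
  }
}
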