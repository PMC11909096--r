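# Optional external assets

This directory ships empty. Two optional files are recognized if you place
them here:

* `puffer_portrait.png` — a grayscale copy of the public-domain Ethel
  Puffer portrait (Wikimedia Commons). When present, the acceptance test
  for the published Balance/DCM worked example runs against it; it is not
  redistributed with the package.
* Pretrained first-layer convolution weights can live anywhere; pass the
  path of the raw little-endian float32 96x3x11x11 tensor (C order:
  filter, channel R/G/B, kernel row, kernel column) to
  `load_filter_bank()` or the CLI flag `--cnn-weights`. The surrogate bank
  is used otherwise.
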