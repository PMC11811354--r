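ATTENUATION MEASUREMENTS:
Liver ([RDE1194] HU) - Spleen ([RDE1207] HU) = [RDE1193] HU
Hepatic steatosis: [yes/no]
Threshold: liver < 40 HU or Liver-Spleen < -10 HU (Hamer O, et al. RadioGraphics 2006)
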