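# Per-dataset detector presets: stride D and sigma, in each dataset's
# native length unit (cm for Synthetic/Cocktail/CoffeeBreak, px for
# IDIAP/GDet).  theta_hat / K are package defaults, not dataset-tuned.
synthetic:
  stride_D: 30
  sigma: 80
idiap:
  stride_D: 20
  sigma: 45
cocktail:
  stride_D: 70
  sigma: 170
coffeebreak:
  stride_D: 30
  sigma: 85
gdet:
  stride_D: 30
  sigma: 200
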