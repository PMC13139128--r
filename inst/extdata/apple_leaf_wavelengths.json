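{
  "description": "Characteristic wavelengths for apple-leaf nitrogen inversion selected by CARS then SPA on Savitzky-Golay second-derivative reflectance (new-shoot-stop-growing stage, n = 125).",
  "wavelengths": [411, 450, 522, 539, 917, 975, 1359, 1425, 2045, 2181, 2215, 2324, 2382, 2387, 2394],
  "n_cars": 102,
  "rmse": 0.1540
}
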