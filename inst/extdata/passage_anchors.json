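{
  "version": "1.0",
  "description": "20-week spontaneous-passage probability anchors for ureteral stone width measured in the bone window, by stone location. Logistic curves are reconstructed through these points on the logit scale.",
  "anchors": [
    {
      "location": "upper",
      "measure": "width",
      "window": "bone",
      "horizon_weeks": 20,
      "points": [
        {"size_mm": 4.2, "probability": 0.73},
        {"size_mm": 5.0, "probability": 0.35}
      ]
    },
    {
      "location": "lower",
      "measure": "width",
      "window": "bone",
      "horizon_weeks": 20,
      "points": [
        {"size_mm": 4.2, "probability": 0.88},
        {"size_mm": 6.0, "probability": 0.62}
      ]
    }
  ]
}
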