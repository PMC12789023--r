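allometry_synthetic.csv
  SYNTHETIC placeholder length-mass coefficients (dry mass mg = a * L^b,
  L in mm), one shared pair (a = 0.05, b = 2.6) across all taxon groups.
  These are stand-in values of a realistic magnitude for grassland
  arthropods, intended for the synthetic pipeline and examples only.
  Analyses of real samples must substitute taxon-specific literature
  coefficients.
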