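# Example bucket scheme: descending-ppm, closed-left/open-right intervals.
# Water, urea and TSP regions are excluded as is standard for urine.
buckets:
  - {id: B1.330, left: 1.35, right: 1.31}   # lactate CH3
  - {id: B1.480, left: 1.50, right: 1.46}   # alanine CH3
  - {id: B1.920, left: 1.94, right: 1.90}   # acetate
  - {id: B2.410, left: 2.43, right: 2.39}   # succinate
  - {id: B2.540, left: 2.56, right: 2.52}   # citrate (half AB)
  - {id: B2.660, left: 2.68, right: 2.64}   # citrate (half AB)
  - {id: B3.050, left: 3.07, right: 3.03}   # creatinine CH3
  - {id: B3.270, left: 3.29, right: 3.25}   # taurine
  - {id: B3.970, left: 3.99, right: 3.95}   # hippurate CH2
  - {id: B7.840, left: 7.86, right: 7.82}   # hippurate aromatic
exclusions:
  - [5.00, 4.50]   # water
  - [6.20, 5.40]   # urea
  - [0.20, -0.20]  # TSP
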