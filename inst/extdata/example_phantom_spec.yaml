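# Example phantom specification: five tissue-equivalent inserts with
# manufacturer QCT densities and pre-measured mean stored grayscales
# (typed-in workflow).  Replace mean_grayscale with an roi block
# ({type: cylinder|line, ...}) to measure from a series instead.
inserts:
- label: insert1
  qct_density_mg_cm3: 0.0
  mean_grayscale: 975.0
- label: insert2
  qct_density_mg_cm3: 100.0
  mean_grayscale: 1100.0
- label: insert3
  qct_density_mg_cm3: 200.0
  mean_grayscale: 1225.0
- label: insert4
  qct_density_mg_cm3: 400.0
  mean_grayscale: 1475.0
- label: insert5
  qct_density_mg_cm3: 800.0
  mean_grayscale: 1975.0
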