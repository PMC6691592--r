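# Template configuration for replicating the observed-data analysis.
# Copy to oxford_wasi_config.yaml next to oxford_wasi_scores.csv (the
# deposited wide-format WASI raw scores, study waves 2-4), and edit the
# column names to match the deposit. Reliabilities/variances rows are
# (vocabulary, reasoning) by wave; they feed the S^2(1 - Rxx) fixed-residual
# adjustment and may be omitted to fit without it. The numbers below are
# placeholders: use the manual-derived internal consistencies and the sample
# variances of the actual deposit.
column_map:
  Voc_W2: voc_t1
  Voc_W3: voc_t2
  Voc_W4: voc_t3
  Mat_W2: mat_t1
  Mat_W3: mat_t2
  Mat_W4: mat_t3
group_col: gender
reliabilities:
  - [0.90, 0.90, 0.90]
  - [0.90, 0.90, 0.90]
variances:
  - [36, 40, 44]
  - [25, 28, 31]
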