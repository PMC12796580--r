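{
  "total_ss": 615.75,
  "subject_ss": 2.75,
  "row": {"ss": 529, "df": 1, "error_ss": 6, "error_df": 3, "F": 264.5, "p": 0.000505769463802},
  "col": {"ss": 56.25, "df": 1, "error_ss": 2.75, "error_df": 3, "F": 61.3636363636364, "p": 0.00433206309859},
  "interaction": {"ss": 9, "df": 1, "error_ss": 10, "error_df": 3, "F": 2.7, "p": 0.198892188137}
}
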