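Packaged plain-text fixtures
============================

discovery_sample_sheet.csv
  Clinical summary of the 21-patient discovery cohort (one record per
  patient; the brain resection sample). Paired blood aliquots exist for
  every patient (paired_blood column); blood-side measurements are not part
  of this table. The published per-patient table gives 2 mMCD, 3 MOGHE,
  1 PMG and 2 non-MCD columns (8 "other pathologies" in total), which this
  transcript follows; the accompanying study-design text states 3 non-MCD
  patients, a discrepancy we preserve rather than resolve. One FCD IIIa
  patient's epilepsy duration is printed as "YE" and is stored as missing,
  and their age at surgery (reconstructed elsewhere as onset + duration) is
  therefore also missing. Risk-factor, prior-surgery and spike-in columns
  are not part of the published table and are left empty.

replication_sample_sheet.csv
  Design layout of the 106-sample replication cohort used for Methyl-qPCR
  validation: 32 paired brain/blood subjects (FCD IIa 15, FCD IIb 12,
  other pathologies 5), 29 unpaired brain samples (11/11/7) and 13 unpaired
  blood samples (IIa 10, IIb 3). Only classification, tissue and pairing
  structure are recorded; clinical covariates were not published for this
  cohort. "Other pathologies" are coded nonMCD.
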