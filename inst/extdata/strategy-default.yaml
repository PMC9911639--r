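name: personalized
prevalence:
  egfr_classic: 0.071
  egfr_nonclassic: 0.01
  alk: 0.02
  ros1: 0.019
  braf: 0.021
  ntrk: 0.002
  kras: 0.25
  met: 0.03
  ret: 0.02
  none: 0.557
pdl1:
  ge50: 0.3
  pd1_49: 0.35
  lt1: 0.35
tree:
  line1:
    egfr_classic:
      mix:
        gefitinib: 0.5
        erlotinib: 0.5
    egfr_nonclassic: afatinib
    alk: alectinib
    ros1: crizotinib
    braf: dabrafenib_trametinib
    ntrk: larotrectinib
    kras: pdl1
    met: pdl1
    ret: pdl1
    none: pdl1
  pdl1_line1:
    ge50:
      mix:
        pembrolizumab: 0.25
        pembro_chemo: 0.75
    pd1_49: pembro_chemo
    lt1: pembro_chemo
  line2:
    alectinib: lorlatinib
    dabrafenib_trametinib: pdl1
    default: chemo
  pdl1_line2:
    ge50: pembrolizumab
    pd1_49: chemo
    lt1: chemo
hr:
  chemo: 1.0
  gefitinib: 0.43
  erlotinib: 0.36
  afatinib: 0.43
  alectinib: 0.47
  crizotinib: 0.45
  dabrafenib_trametinib: 0.56
  larotrectinib: 0.82
  pembrolizumab: 0.5
  pembro_chemo: 0.52
  lorlatinib: 0.4
prognostic_hr:
  egfr_classic: 0.82
  alk: 0.8
wearout:
  gefitinib: 15.0
  erlotinib: 15.0
  afatinib: 15.0
  crizotinib: 15.0
  dabrafenib_trametinib: 15.0
  larotrectinib: 15.0
cure:
  pembrolizumab: 0.23
  pembro_chemo: 0.23
class:
  chemo: chemo
  gefitinib: targeted
  erlotinib: targeted
  afatinib: targeted
  alectinib: targeted
  crizotinib: targeted
  dabrafenib_trametinib: targeted
  larotrectinib: targeted
  lorlatinib: targeted
  pembrolizumab: immunotherapy
  pembro_chemo: immunotherapy
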