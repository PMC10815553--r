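# Illustrative activation-state reference rectangles (Angstrom) for block
# classification. These bounds are configuration, not canon: tune them to
# the receptor and descriptor pair under study.
pairs:
  - x: edry_ionic
    y: npxxy_ca
    regions:
      active: {xmin: 17.0, xmax: 23.0, ymin: 7.5, ymax: 10.5}
      inactive: {xmin: 2.0, xmax: 6.0, ymin: 10.6, ymax: 13.0}
  - x: pif_36
    y: pif_56
    regions:
      active: {xmin: 8.0, xmax: 10.0, ymin: 12.5, ymax: 14.0}
      inactive: {xmin: 10.5, xmax: 12.5, ymin: 11.0, ymax: 12.4}
  - x: lbs_tightening
    y: npxxy_hbond
    regions:
      active: {xmin: 10.0, xmax: 12.0, ymin: 1.5, ymax: 3.0}
      inactive: {xmin: 12.1, xmax: 14.0, ymin: 4.0, ymax: 6.5}
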