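# Illustrative map for an M3 mAChR construct. The M3 rule additionally
# needs K7.32 and E45.49 (salt-bridge metric). Verify residue numbers
# against your construct's numbering.
subtype: M3
entries:
  - {bw: "2.64", resnum: 127, resname: TYR}
  - {bw: "45.49", resnum: 218, resname: GLU}
  - {bw: "45.50", resnum: 219, resname: CYS}
  - {bw: "45.51", resnum: 220}
  - {bw: "7.32", resnum: 521, resname: LYS}
  - {bw: "7.36", resnum: 525, resname: ASN}
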