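# Illustrative map for an M4 mAChR construct. The Inactive-Apo rule
# needs the whole ECL2 range 45.49-45.51. Verify residue numbers
# against your construct's numbering.
subtype: M4
entries:
  - {bw: "2.64", resnum: 89, resname: TYR}
  - {bw: "45.49", resnum: 181, resname: GLN}
  - {bw: "45.50", resnum: 182, resname: CYS}
  - {bw: "45.51", resnum: 183}
  - {bw: "7.32", resnum: 426}
  - {bw: "7.36", resnum: 430, resname: SER}
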