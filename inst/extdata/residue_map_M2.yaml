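# Illustrative map for an M2 mAChR construct (position 7.36 is THR in
# M2). Verify residue numbers against your construct's numbering.
subtype: M2
entries:
  - {bw: "2.64", resnum: 80, resname: TYR}
  - {bw: "45.49", resnum: 172}
  - {bw: "45.50", resnum: 173, resname: CYS}
  - {bw: "45.51", resnum: 174}
  - {bw: "7.32", resnum: 418}
  - {bw: "7.36", resnum: 422, resname: THR}
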