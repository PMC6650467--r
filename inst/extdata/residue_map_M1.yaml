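# Illustrative Ballesteros-Weinstein residue map for an M1 mAChR
# construct. Residue numbers follow the topology's own (author)
# numbering and MUST be verified against your construct before use;
# only labels used by the pocket rules are listed.
subtype: M1
entries:
  - {bw: "2.61", resnum: 82, resname: TYR}
  - {bw: "2.64", resnum: 85, resname: TYR}
  - {bw: "45.49", resnum: 177}
  - {bw: "45.50", resnum: 178, resname: CYS}
  - {bw: "45.51", resnum: 179}
  - {bw: "7.32", resnum: 392}
  - {bw: "7.36", resnum: 396, resname: GLU}
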