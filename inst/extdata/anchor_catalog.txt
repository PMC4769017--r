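# Kinase-domain anchor catalog (PROSITE syntax).
# The two literal anchors flank the MAPK activation segment.
n_anchor: H-R-D-L-K-P-N
c_anchor: T-R-W-Y-R-A-P
max_mismatches: 2
first_residues: T,S,K
offset_min: 4
offset_max: 14
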