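# Literature per-order mean radii for the rat renal arterial tree
# (morphometric casting data; orders 0-2 and the root order 10).
# These are published reference values shipped for correlation reporting;
# they are NOT produced by this package. sd is NA where not quoted.
order,mean_radius_um,sd_radius_um
0,10.08,0.14
1,13.90,NA
2,20.06,NA
10,216.10,4.74
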