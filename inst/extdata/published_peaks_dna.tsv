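# Negative-mode peak positions read off the published telomeric-DNA
# spectra (free quadruplex and 1:1-complex ammonium ladders, z = -5);
# unit areas, positions only. Matched in analysis/01_mass_and_ions.R.
#@ polarity negative
#@ ligand TMPyP4
1698.5505	1
1701.5393	1
1705.0401	1
1833.1813	1
1836.6714	1
1840.7173	1
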