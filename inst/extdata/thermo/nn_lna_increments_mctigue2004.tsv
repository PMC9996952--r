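# Single-substitution LNA perturbation increments for LNA-DNA/DNA duplexes.
# McTigue PM, Peterson RJ, Kahn JD (2004) Biochemistry 43:5388-5405,
# "Sequence-dependent thermodynamic parameters for locked nucleic acid
# (LNA)-DNA duplex formation".
# ddH in kcal/mol, ddS in cal/(mol K); the increment for an LNA residue at
# position i is indexed by the dinucleotide (i, i+1) of the oligo with the
# LNA as the 5' residue of the dimer. A 3'-terminal LNA contributes no
# increment. These parameters describe isolated substitutions; stacking
# cooperativity between consecutive LNA residues is not modeled, so fully
# substituted oligos are under-estimated relative to vendor predictions.
# table_version: 1.0
dimer	ddH_kcal	ddS_eu
AA	0.707	2.477
AC	1.131	4.064
AG	0.264	2.613
AT	2.282	7.457
CA	1.049	4.320
CC	2.096	7.996
CG	0.785	3.709
CT	0.708	4.175
GA	3.162	10.544
GC	-0.360	-0.251
GG	-2.844	-6.680
GT	-0.212	-0.318
TA	-0.046	1.153
TC	1.893	6.845
TG	1.376	5.758
TT	0.522	2.898
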