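# Published QM/MM oxygen binding energies (kcal/mol) for human hemoglobin
# subunits in the R and T quaternary states, wild type plus distal (HE7G)
# and proximal (HF8G+Im) mutants.
# Wild-type dE values are published directly (source=dE). Mutant dE values
# are reconstructed as dE_wt + ddE from the published mutant shifts
# (ddE_HE7G: alphaT -0.1, alphaR -0.2, betaT 0.9, betaR 2.5;
#  ddE_HF8G+Im: alphaT -4.3, alphaR 2.8, betaT 3.9, betaR 4.7);
# they are arithmetic reconstructions, not published absolute energies.
subunit	state	variant	dE	source
alpha	T	wt	-23.1	dE
alpha	R	wt	-30.2	dE
beta	T	wt	-21.7	dE
beta	R	wt	-30.7	dE
alpha	T	HE7G	-23.2	dE
alpha	R	HE7G	-30.4	dE
beta	T	HE7G	-20.8	dE
beta	R	HE7G	-28.2	dE
alpha	T	HF8G+Im	-27.4	dE
alpha	R	HF8G+Im	-27.4	dE
beta	T	HF8G+Im	-17.8	dE
beta	R	HF8G+Im	-26.0	dE
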