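# Phosphosite annotations for the peptide fixtures (1-based positions within
# each peptide sequence). Editable configuration, not hard-coded truth:
# Tau1 sites correspond to pT175/pT181 and Tau2 to pT231/pS235/pS237/pS238 in
# tau numbering; bCPP carries the standard tetraphosphorylated form of the
# beta-casein 1-25 peptide and Stath the two N-terminal phosphoserines of
# statherin.
peptide	sites
Tau1	4,10
Tau2	7,11,13,14
bCPP	15,17,18,19
Stath	2,3
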