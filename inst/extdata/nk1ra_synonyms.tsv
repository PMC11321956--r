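# Verbatim name -> standardized generic name (tab-separated).
# Covers the brand/generic identities of the three NK-1 receptor
# antagonists; real analyses supply a much larger dictionary.
APREPITANT	aprepitant
EMEND	aprepitant
CINVANTI	aprepitant
FOSAPREPITANT	fosaprepitant
FOSAPREPITANT DIMEGLUMINE	fosaprepitant
EMEND FOR INJECTION	fosaprepitant
IVEMEND	fosaprepitant
NETUPITANT	netupitant
NETUPITANT/PALONOSETRON	netupitant
AKYNZEO	netupitant
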