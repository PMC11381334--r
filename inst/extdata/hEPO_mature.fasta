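>hEPO_mature human erythropoietin, mature chain (166 aa, signal peptide removed)
APPRLICDSRVLERYLLEAKEAENITTGCAEHCSLNENITVPDTKVNFYAWKRMEVGQQA
VEVWQGLALLSEAVLRGQALLVNSSQPWEPLQLHVDKAVSGLRSLTTLLRALGAQKEAIS
PPDAASAAPLRTITADTFRKLFRVYSNFLRGKLKLYTGEACRTGDR
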