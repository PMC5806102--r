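{"cutoff":-0.154,"horizon":60,"provenance":"published seven-pair gastric-cancer signature (GPL570 microarray cohorts); coefficients from L1-penalised Cox selection on a 300-sample training set"}
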