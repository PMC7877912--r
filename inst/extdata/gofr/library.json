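{"r_R_MD":1.47,"r_P_MD":1.81,"trunc_nm":20}
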