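response,tn,fn,fp,tp
lemna_minor,83,36,17,39
spirodela_polyrhiza,99,45,11,20
wolffia,115,37,6,17
floating_group,75,29,20,51
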