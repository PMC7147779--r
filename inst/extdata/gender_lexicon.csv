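term,weight
cute,60
hair,60
bestie,60
makeup,60
dress,60
nails,60
mascara,60
game,-60
bro,-60
team,-60
beard,-60
football,-60
truck,-60
gym,-60
_intercept,0
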