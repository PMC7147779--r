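term,weight
work,90.9
office,90.9
meeting,90.9
taxes,90.9
coffee,90.9
news,90.9
morning,90.9
budget,90.9
lol,-90.9
omg,-90.9
school,-90.9
homework,-90.9
lmao,-90.9
literally,-90.9
snap,-90.9
idk,-90.9
_intercept,35.5
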