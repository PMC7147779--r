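term
depressed
depression
depressive
suicidal
selfharm
anxiety
anxious
insomnia
worthless
hopeless
lonely
broken
sadness
misery
grief
despair
numb
empty
crying
hurting
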