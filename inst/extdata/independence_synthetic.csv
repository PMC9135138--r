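x,y
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,b
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
a,d
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,b
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
c,d
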