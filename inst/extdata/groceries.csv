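age,bread,onions,butter
A,y,n,y
A,y,y,y
B,y,n,y
B,n,n,y
A,n,n,y
B,y,y,y
A,y,n,y
B,y,n,y
A,n,n,n
B,y,y,y
A,y,y,y
B,n,n,n
C,y,n,y
C,n,y,n
C,n,n,n
C,y,y,n
A,n,y,n
B,n,y,n
C,n,y,y
C,,y,n
A,n,y,n
C,n,n,n
B,n,y,y
C,n,y,n
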