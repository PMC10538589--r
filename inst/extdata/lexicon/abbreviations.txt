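q
hr
hrs
mg
mcg
ml
iv
im
sc
po
prn
bid
tid
qid
qd
qh
dr
mr
mrs
ms
st
vs
am
pm
etc
eg
ie
approx
wk
mo
yr
pt
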