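phone,class,f1,f2,f3,f4,f5,f6,f7,f8,f9,f10,f11,f12,f13,f14,f15,f16,f17,f18,f19,f20
b,consonant,1,0,1,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
p,consonant,1,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
m,consonant,1,0,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
f,consonant,1,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0
v,consonant,1,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0
w,consonant,1,0,1,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,1,0
t,consonant,1,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0
d,consonant,1,0,1,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0
s,consonant,1,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0
z,consonant,1,0,1,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0
n,consonant,1,0,1,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0
l,consonant,1,0,1,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0
r,consonant,1,0,1,0,0,0,0,1,0,1,0,0,0,0,0,0,1,0,0,0
th,consonant,1,0,0,0,0,1,0,0,0,1,0,0,0,0,0,1,0,0,0,0
dh,consonant,1,0,1,0,0,1,0,0,0,1,0,0,0,0,0,1,0,0,0,0
sh,consonant,1,0,0,0,0,1,0,0,0,1,0,0,1,0,0,0,0,0,0,0
zh,consonant,1,0,1,0,0,1,0,0,0,1,0,0,1,0,0,0,0,0,0,0
ch,consonant,1,0,0,0,0,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0
j,consonant,1,0,1,0,0,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0
y,consonant,1,0,1,0,0,0,0,1,0,0,1,0,1,0,0,1,0,0,0,0
k,consonant,1,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
g,consonant,1,0,1,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
ng,consonant,1,0,1,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
x,consonant,1,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0
q,consonant,1,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0
h,consonant,1,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0
a,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0
e,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0
i,vowel,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0
o,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,1,1,0
u,vowel,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0,1,1,0
aa,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,1
ee,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1
ii,vowel,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,0,1
oo,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,1,1,1
uu,vowel,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0,1,1,1
ai,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0,1
au,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,1,1,1
oi,vowel,0,1,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,1,1
#,seg,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
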