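class,increment
C.ar,0.31
C.3.h3,0.53
C.3.h2,0.36
C.3.h1,0.13
C.3.h0,0.20
C.3.het,-0.10
C.2.plain,0.38
C.2.carbonyl,-0.05
C.1,0.21
N.amine,-0.60
N.am,-0.55
N.ar,-0.40
N.1,-0.20
N.pl3,-0.50
N.2,-0.45
N.plus,-1.00
O.3.hydroxyl,-0.46
O.3.ether,0.05
O.2,-0.14
O.co2,-0.50
S.3,0.45
S.2,0.40
S.thiol,-0.10
P,-0.50
F,0.20
Cl,0.64
Br,0.88
I,1.12
other,0.00
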