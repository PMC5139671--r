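aa	chi1	chi2	chi3	chi4	probability
A	NA	NA	NA	NA	1.0
G	NA	NA	NA	NA	1.0
S	-65	NA	NA	NA	0.48
S	62	NA	NA	NA	0.30
S	180	NA	NA	NA	0.22
C	-65	NA	NA	NA	0.55
C	180	NA	NA	NA	0.25
C	62	NA	NA	NA	0.20
T	-60	NA	NA	NA	0.50
T	60	NA	NA	NA	0.43
T	180	NA	NA	NA	0.07
V	175	NA	NA	NA	0.73
V	-60	NA	NA	NA	0.20
V	60	NA	NA	NA	0.07
L	-65	175	NA	NA	0.62
L	180	65	NA	NA	0.29
L	65	175	NA	NA	0.09
I	-65	170	NA	NA	0.60
I	180	165	NA	NA	0.15
I	-60	-60	NA	NA	0.15
I	62	170	NA	NA	0.10
M	-65	180	75	NA	0.30
M	-65	180	-75	NA	0.30
M	180	180	75	NA	0.20
M	180	180	180	NA	0.20
P	-25	40	NA	NA	0.55
P	25	-35	NA	NA	0.45
D	-70	-15	NA	NA	0.51
D	180	0	NA	NA	0.33
D	65	10	NA	NA	0.16
N	-65	-20	NA	NA	0.45
N	180	30	NA	NA	0.33
N	65	40	NA	NA	0.22
E	-65	180	-10	NA	0.40
E	180	180	0	NA	0.35
E	65	180	0	NA	0.25
Q	-65	180	-25	NA	0.42
Q	180	180	0	NA	0.33
Q	65	180	20	NA	0.25
K	-65	180	180	180	0.50
K	180	180	180	180	0.35
K	65	180	180	180	0.15
R	-65	180	180	180	0.45
R	180	180	180	180	0.35
R	65	180	180	180	0.20
H	-65	-70	NA	NA	0.45
H	180	-75	NA	NA	0.35
H	65	-70	NA	NA	0.20
F	-65	90	NA	NA	0.50
F	180	80	NA	NA	0.35
F	65	90	NA	NA	0.15
Y	-65	90	NA	NA	0.50
Y	180	80	NA	NA	0.35
Y	65	90	NA	NA	0.15
W	-65	100	NA	NA	0.40
W	180	75	NA	NA	0.35
W	65	-90	NA	NA	0.25
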