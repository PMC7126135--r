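# Background amino-acid frequencies: reconstruction of UniProtKB
# natural-abundance statistics (2019-era snapshot). Synthetic in the sense
# that the exact release statistics table is not redistributed here; the
# arginine value 0.0569 is pinned so that log2(1/Q(R)) = 4.1354 bits, and
# the remaining residues carry representative UniProtKB abundances.
symbol	frequency
A	0.0907
R	0.0569
N	0.0382
D	0.0547
C	0.0123
Q	0.0379
E	0.0618
G	0.0736
H	0.0220
I	0.0555
L	0.0987
K	0.0492
M	0.0238
F	0.0392
P	0.0484
S	0.0682
T	0.0554
W	0.0131
Y	0.0291
V	0.0687
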