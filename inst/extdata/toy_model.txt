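# tcrenrich recombination model, format v1
[v_segments]
TRBV1 TGTGCCAGCAGTTTATCG
TRBV2 TGTGCCACCAGCAGAGAT
TRBV3 TGTGCTGTGAGTGAAAGG
[j_segments]
TRBJ1 AATGAGCAGTTCTTT
TRBJ2 TATGGCTACACCTTC
TRBJ3 TACAATGAGCAGTTC
[vj_usage]
TRBV1 TRBJ1 0.20000000000000001
TRBV1 TRBJ2 0.17499999999999999
TRBV1 TRBJ3 0.125
TRBV2 TRBJ1 0.12
TRBV2 TRBJ2 0.105
TRBV2 TRBJ3 0.074999999999999997
TRBV3 TRBJ1 0.080000000000000016
TRBV3 TRBJ2 0.069999999999999993
TRBV3 TRBJ3 0.050000000000000003
[v_trim]
TRBV1 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
TRBV2 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
TRBV3 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
[j_trim]
TRBJ1 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
TRBJ2 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
TRBJ3 0.34999999999999998 0.25 0.17999999999999999 0.12 0.070000000000000007 0.029999999999999999
[ins_len]
0.049977131000323513 0.14993139300097055 0.22489708950145579 0.22489708950145584 0.16867281712609186 0.10120369027565511 0.050601845137827554 0.021686505059068956 0.0081324393971508573
[ins_nt]
order0
0.20000000000000001 0.29999999999999999 0.29999999999999999 0.20000000000000001
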