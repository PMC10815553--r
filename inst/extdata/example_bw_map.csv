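generic_number,helix,residue_id,residue_name
3.32,3,332,D
3.39,3,339,S
3.40,3,340,I
3.44,3,344,C
3.50,3,350,R
5.46,5,546,S
5.50,5,550,P
6.29,6,629,R
6.30,6,630,E
6.44,6,644,F
7.42,7,742,A
7.49,7,749,N
7.53,7,753,Y
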