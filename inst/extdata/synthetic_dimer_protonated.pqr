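REMARK  Synthetic protonated-template donor matching synthetic_dimer.pqr.
REMARK  Same heavy-atom coordinates; residues carry protonated variants:
REMARK  ASH/GLH neutral carboxylic acids (extra HD2/HE2), HIP doubly
REMARK  protonated histidine (+1, extra HD1).
ATOM      1  N    ASH A   89      10.000  10.000  10.000  -0.3000  1.5000
ATOM      2  CA   ASH A   89      11.400  10.000  10.000   0.1000  1.7000
ATOM      3  C    ASH A   89      12.100  11.300  10.000   0.5000  1.7000
ATOM      4  O    ASH A   89      11.500  12.400  10.000  -0.3000  1.4000
ATOM      5  CB   ASH A   89      12.200   8.800  10.500   0.0000  1.7000
ATOM      6  CG   ASH A   89      12.300   7.700   9.500   0.6500  1.7000
ATOM      7  OD1  ASH A   89      11.600   7.700   8.500  -0.5500  1.4000
ATOM      8  OD2  ASH A   89      13.100   6.700   9.700  -0.6000  1.4000
ATOM      9  HD2  ASH A   89      13.200   6.100   8.900   0.5000  1.0000
ATOM     10  N    GLH A   91      15.000  10.000  10.000  -0.3000  1.5000
ATOM     11  CA   GLH A   91      16.400  10.000  10.000   0.1000  1.7000
ATOM     12  C    GLH A   91      17.100  11.300  10.000   0.5000  1.7000
ATOM     13  O    GLH A   91      16.500  12.400  10.000  -0.3000  1.4000
ATOM     14  CB   GLH A   91      17.200   8.800  10.500   0.0000  1.7000
ATOM     15  CG   GLH A   91      17.300   7.600   9.600   0.0000  1.7000
ATOM     16  CD   GLH A   91      18.100   6.500  10.200   0.6500  1.7000
ATOM     17  OE1  GLH A   91      18.800   6.700  11.200  -0.5500  1.4000
ATOM     18  OE2  GLH A   91      18.100   5.400   9.600  -0.6000  1.4000
ATOM     19  HE2  GLH A   91      18.600   4.700   9.900   0.5000  1.0000
ATOM     20  N    HIP B   46      20.000  20.000  20.000  -0.3000  1.5000
ATOM     21  CA   HIP B   46      21.400  20.000  20.000   0.1000  1.7000
ATOM     22  C    HIP B   46      22.100  21.300  20.000   0.5000  1.7000
ATOM     23  O    HIP B   46      21.500  22.400  20.000  -0.3000  1.4000
ATOM     24  CB   HIP B   46      22.200  18.800  20.500   0.0000  1.7000
ATOM     25  CG   HIP B   46      22.300  17.700  19.500   0.1000  1.7000
ATOM     26  ND1  HIP B   46      21.600  16.600  19.600  -0.3000  1.5000
ATOM     27  HD1  HIP B   46      21.000  16.500  20.300   0.4000  1.0000
ATOM     28  CD2  HIP B   46      23.000  17.500  18.400   0.1500  1.7000
ATOM     29  CE1  HIP B   46      21.900  15.800  18.600   0.3000  1.7000
ATOM     30  NE2  HIP B   46      22.800  16.300  17.800  -0.2500  1.5000
ATOM     31  HE2  HIP B   46      23.200  15.900  17.000   0.6000  1.0000
ATOM     32  N    GLH B  102      25.000  20.000  20.000  -0.3000  1.5000
ATOM     33  CA   GLH B  102      26.400  20.000  20.000   0.1000  1.7000
ATOM     34  C    GLH B  102      27.100  21.300  20.000   0.5000  1.7000
ATOM     35  O    GLH B  102      26.500  22.400  20.000  -0.3000  1.4000
ATOM     36  CB   GLH B  102      27.200  18.800  20.500   0.0000  1.7000
ATOM     37  CG   GLH B  102      27.300  17.600  19.600   0.0000  1.7000
ATOM     38  CD   GLH B  102      28.100  16.500  20.200   0.6500  1.7000
ATOM     39  OE1  GLH B  102      28.800  16.700  21.200  -0.5500  1.4000
ATOM     40  OE2  GLH B  102      28.100  15.400  19.600  -0.6000  1.4000
ATOM     41  HE2  GLH B  102      28.600  14.700  19.900   0.5000  1.0000
ATOM     42  N    HIP B  106      30.000  20.000  20.000  -0.3000  1.5000
ATOM     43  CA   HIP B  106      31.400  20.000  20.000   0.1000  1.7000
ATOM     44  C    HIP B  106      32.100  21.300  20.000   0.5000  1.7000
ATOM     45  O    HIP B  106      31.500  22.400  20.000  -0.3000  1.4000
ATOM     46  CB   HIP B  106      32.200  18.800  20.500   0.0000  1.7000
ATOM     47  CG   HIP B  106      32.300  17.700  19.500   0.1000  1.7000
ATOM     48  ND1  HIP B  106      31.600  16.600  19.600  -0.3000  1.5000
ATOM     49  HD1  HIP B  106      31.000  16.500  20.300   0.4000  1.0000
ATOM     50  CD2  HIP B  106      33.000  17.500  18.400   0.1500  1.7000
ATOM     51  CE1  HIP B  106      31.900  15.800  18.600   0.3000  1.7000
ATOM     52  NE2  HIP B  106      32.800  16.300  17.800  -0.2500  1.5000
ATOM     53  HE2  HIP B  106      33.200  15.900  17.000   0.6000  1.0000
TER
END
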