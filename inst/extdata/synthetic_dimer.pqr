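REMARK  Synthetic H2A-H2B-like test structure (not experimental coordinates).
REMARK  Chain A mimics H2A (ASP 89, GLU 91), chain B mimics H2B
REMARK  (HIS 46, GLU 102, HIS 106). Default protonation states:
REMARK  carboxylates deprotonated (-1), histidines neutral (0).
ATOM      1  N    ASP A   89      10.000  10.000  10.000  -0.3000  1.5000
ATOM      2  CA   ASP A   89      11.400  10.000  10.000   0.1000  1.7000
ATOM      3  C    ASP A   89      12.100  11.300  10.000   0.5000  1.7000
ATOM      4  O    ASP A   89      11.500  12.400  10.000  -0.3000  1.4000
ATOM      5  CB   ASP A   89      12.200   8.800  10.500   0.0000  1.7000
ATOM      6  CG   ASP A   89      12.300   7.700   9.500   0.8000  1.7000
ATOM      7  OD1  ASP A   89      11.600   7.700   8.500  -0.9000  1.4000
ATOM      8  OD2  ASP A   89      13.100   6.700   9.700  -0.9000  1.4000
ATOM      9  N    GLU A   91      15.000  10.000  10.000  -0.3000  1.5000
ATOM     10  CA   GLU A   91      16.400  10.000  10.000   0.1000  1.7000
ATOM     11  C    GLU A   91      17.100  11.300  10.000   0.5000  1.7000
ATOM     12  O    GLU A   91      16.500  12.400  10.000  -0.3000  1.4000
ATOM     13  CB   GLU A   91      17.200   8.800  10.500   0.0000  1.7000
ATOM     14  CG   GLU A   91      17.300   7.600   9.600   0.0000  1.7000
ATOM     15  CD   GLU A   91      18.100   6.500  10.200   0.8000  1.7000
ATOM     16  OE1  GLU A   91      18.800   6.700  11.200  -0.9000  1.4000
ATOM     17  OE2  GLU A   91      18.100   5.400   9.600  -0.9000  1.4000
ATOM     18  N    HIS B   46      20.000  20.000  20.000  -0.3000  1.5000
ATOM     19  CA   HIS B   46      21.400  20.000  20.000   0.1000  1.7000
ATOM     20  C    HIS B   46      22.100  21.300  20.000   0.5000  1.7000
ATOM     21  O    HIS B   46      21.500  22.400  20.000  -0.3000  1.4000
ATOM     22  CB   HIS B   46      22.200  18.800  20.500   0.0000  1.7000
ATOM     23  CG   HIS B   46      22.300  17.700  19.500   0.1000  1.7000
ATOM     24  ND1  HIS B   46      21.600  16.600  19.600  -0.5500  1.5000
ATOM     25  CD2  HIS B   46      23.000  17.500  18.400   0.1000  1.7000
ATOM     26  CE1  HIS B   46      21.900  15.800  18.600   0.3000  1.7000
ATOM     27  NE2  HIS B   46      22.800  16.300  17.800  -0.2500  1.5000
ATOM     28  HE2  HIS B   46      23.200  15.900  17.000   0.3000  1.0000
ATOM     29  N    GLU B  102      25.000  20.000  20.000  -0.3000  1.5000
ATOM     30  CA   GLU B  102      26.400  20.000  20.000   0.1000  1.7000
ATOM     31  C    GLU B  102      27.100  21.300  20.000   0.5000  1.7000
ATOM     32  O    GLU B  102      26.500  22.400  20.000  -0.3000  1.4000
ATOM     33  CB   GLU B  102      27.200  18.800  20.500   0.0000  1.7000
ATOM     34  CG   GLU B  102      27.300  17.600  19.600   0.0000  1.7000
ATOM     35  CD   GLU B  102      28.100  16.500  20.200   0.8000  1.7000
ATOM     36  OE1  GLU B  102      28.800  16.700  21.200  -0.9000  1.4000
ATOM     37  OE2  GLU B  102      28.100  15.400  19.600  -0.9000  1.4000
ATOM     38  N    HIS B  106      30.000  20.000  20.000  -0.3000  1.5000
ATOM     39  CA   HIS B  106      31.400  20.000  20.000   0.1000  1.7000
ATOM     40  C    HIS B  106      32.100  21.300  20.000   0.5000  1.7000
ATOM     41  O    HIS B  106      31.500  22.400  20.000  -0.3000  1.4000
ATOM     42  CB   HIS B  106      32.200  18.800  20.500   0.0000  1.7000
ATOM     43  CG   HIS B  106      32.300  17.700  19.500   0.1000  1.7000
ATOM     44  ND1  HIS B  106      31.600  16.600  19.600  -0.5500  1.5000
ATOM     45  CD2  HIS B  106      33.000  17.500  18.400   0.1000  1.7000
ATOM     46  CE1  HIS B  106      31.900  15.800  18.600   0.3000  1.7000
ATOM     47  NE2  HIS B  106      32.800  16.300  17.800  -0.2500  1.5000
ATOM     48  HE2  HIS B  106      33.200  15.900  17.000   0.3000  1.0000
TER
END
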