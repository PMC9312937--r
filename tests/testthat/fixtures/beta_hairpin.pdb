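ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       1.864   2.176   0.962  1.00  0.00              
ATOM      5  N   ALA A   2       2.656   1.800  -1.098  1.00  0.00              
ATOM      6  CA  ALA A   2       3.232   3.134  -1.226  1.00  0.00              
ATOM      7  C   ALA A   2       4.743   3.066  -1.421  1.00  0.00              
ATOM      8  O   ALA A   2       5.247   2.591  -2.438  1.00  0.00              
ATOM      9  N   ALA A   3       5.484   3.548  -0.429  1.00  0.00              
ATOM     10  CA  ALA A   3       6.941   3.543  -0.489  1.00  0.00              
ATOM     11  C   ALA A   3       7.501   4.960  -0.423  1.00  0.00              
ATOM     12  O   ALA A   3       7.399   5.653   0.590  1.00  0.00              
ATOM     13  N   ALA A   4       8.104   5.404  -1.520  1.00  0.00              
ATOM     14  CA  ALA A   4       8.683   6.741  -1.589  1.00  0.00              
ATOM     15  C   ALA A   4      10.184   6.680  -1.849  1.00  0.00              
ATOM     16  O   ALA A   4      10.643   6.268  -2.914  1.00  0.00              
ATOM     17  N   ALA A   5      10.968   7.096  -0.860  1.00  0.00              
ATOM     18  CA  ALA A   5      12.421   7.090  -0.980  1.00  0.00              
ATOM     19  C   ALA A   5      12.992   8.498  -0.849  1.00  0.00              
ATOM     20  O   ALA A   5      12.936   9.126   0.208  1.00  0.00              
ATOM     21  N   ALA A   6      13.553   9.008  -1.940  1.00  0.00              
ATOM     22  CA  ALA A   6      14.136  10.344  -1.949  1.00  0.00              
ATOM     23  C   ALA A   6      13.094  11.403  -1.606  1.00  0.00              
ATOM     24  O   ALA A   6      12.082  11.565  -2.289  1.00  0.00              
ATOM     25  N   ALA A   7      13.339  12.141  -0.528  1.00  0.00              
ATOM     26  CA  ALA A   7      12.423  13.187  -0.091  1.00  0.00              
ATOM     27  C   ALA A   7      11.243  12.601   0.677  1.00  0.00              
ATOM     28  O   ALA A   7      10.348  13.312   1.136  1.00  0.00              
ATOM     29  N   ALA A   8      11.235  11.280   0.822  1.00  0.00              
ATOM     30  CA  ALA A   8      10.164  10.594   1.535  1.00  0.00              
ATOM     31  C   ALA A   8       9.431   9.617   0.622  1.00  0.00              
ATOM     32  O   ALA A   8       9.978   8.609   0.176  1.00  0.00              
ATOM     33  N   ALA A   9       8.168   9.916   0.336  1.00  0.00              
ATOM     34  CA  ALA A   9       7.356   9.065  -0.525  1.00  0.00              
ATOM     35  C   ALA A   9       6.138   8.530   0.220  1.00  0.00              
ATOM     36  O   ALA A   9       5.227   9.269   0.595  1.00  0.00              
ATOM     37  N   ALA A  10       6.115   7.219   0.441  1.00  0.00              
ATOM     38  CA  ALA A  10       5.008   6.580   1.143  1.00  0.00              
ATOM     39  C   ALA A  10       4.312   5.553   0.255  1.00  0.00              
ATOM     40  O   ALA A  10       4.873   4.518  -0.105  1.00  0.00              
ATOM     41  N   ALA A  11       3.066   5.839  -0.107  1.00  0.00              
ATOM     42  CA  ALA A  11       2.289   4.942  -0.954  1.00  0.00              
ATOM     43  C   ALA A  11       1.034   4.455  -0.237  1.00  0.00              
ATOM     44  O   ALA A  11       0.112   5.218   0.051  1.00  0.00              
ATOM     45  N   ALA A  12       0.993   3.160   0.060  1.00  0.00              
ATOM     46  CA  ALA A  12      -0.149   2.567   0.745  1.00  0.00              
ATOM     47  C   ALA A  12      -0.809   1.492  -0.113  1.00  0.00              
ATOM     48  O   ALA A  12      -0.219   0.443  -0.373  1.00  0.00              
END   
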