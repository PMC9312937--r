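ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       2.909   1.771  -0.764  1.00  0.00              
ATOM      5  N   ALA A   2       1.463   2.263   0.872  1.00  0.00              
ATOM      6  CA  ALA A   2       1.899   3.650   0.974  1.00  0.00              
ATOM      7  C   ALA A   2       1.768   4.370  -0.364  1.00  0.00              
ATOM      8  O   ALA A   2       2.676   5.064  -0.821  1.00  0.00              
ATOM      9  N   ALA A   3       0.618   4.205  -1.008  1.00  0.00              
ATOM     10  CA  ALA A   3       0.364   4.838  -2.297  1.00  0.00              
ATOM     11  C   ALA A   3       1.421   4.443  -3.323  1.00  0.00              
ATOM     12  O   ALA A   3       1.974   5.277  -4.041  1.00  0.00              
ATOM     13  N   ALA A   4       1.711   3.149  -3.398  1.00  0.00              
ATOM     14  CA  ALA A   4       2.704   2.639  -4.337  1.00  0.00              
ATOM     15  C   ALA A   4       4.057   3.309  -4.126  1.00  0.00              
ATOM     16  O   ALA A   4       4.718   3.752  -5.066  1.00  0.00              
ATOM     17  N   ALA A   5       4.484   3.388  -2.870  1.00  0.00              
ATOM     18  CA  ALA A   5       5.761   4.005  -2.531  1.00  0.00              
ATOM     19  C   ALA A   5       5.830   5.442  -3.035  1.00  0.00              
ATOM     20  O   ALA A   5       6.810   5.873  -3.642  1.00  0.00              
ATOM     21  N   ALA A   6       4.771   6.204  -2.781  1.00  0.00              
ATOM     22  CA  ALA A   6       4.709   7.597  -3.208  1.00  0.00              
ATOM     23  C   ALA A   6       4.899   7.721  -4.716  1.00  0.00              
ATOM     24  O   ALA A   6       5.669   8.546  -5.209  1.00  0.00              
ATOM     25  N   ALA A   7       4.187   6.887  -5.467  1.00  0.00              
ATOM     26  CA  ALA A   7       4.276   6.902  -6.922  1.00  0.00              
ATOM     27  C   ALA A   7       5.712   6.685  -7.389  1.00  0.00              
ATOM     28  O   ALA A   7       6.229   7.394  -8.252  1.00  0.00              
ATOM     29  N   ALA A   8       6.372   5.687  -6.812  1.00  0.00              
ATOM     30  CA  ALA A   8       7.751   5.373  -7.167  1.00  0.00              
ATOM     31  C   ALA A   8       8.660   6.581  -6.968  1.00  0.00              
ATOM     32  O   ALA A   8       9.471   6.933  -7.825  1.00  0.00              
ATOM     33  N   ALA A   9       8.528   7.232  -5.817  1.00  0.00              
ATOM     34  CA  ALA A   9       9.336   8.403  -5.502  1.00  0.00              
ATOM     35  C   ALA A   9       9.171   9.489  -6.560  1.00  0.00              
ATOM     36  O   ALA A   9      10.138  10.072  -7.050  1.00  0.00              
ATOM     37  N   ALA A  10       7.924   9.768  -6.925  1.00  0.00              
ATOM     38  CA  ALA A  10       7.629  10.785  -7.927  1.00  0.00              
ATOM     39  C   ALA A  10       8.339  10.485  -9.243  1.00  0.00              
ATOM     40  O   ALA A  10       8.962  11.350  -9.858  1.00  0.00              
ATOM     41  N   ALA A  11       8.247   9.236  -9.688  1.00  0.00              
ATOM     42  CA  ALA A  11       8.881   8.818 -10.933  1.00  0.00              
ATOM     43  C   ALA A  11      10.381   9.091 -10.908  1.00  0.00              
ATOM     44  O   ALA A  11      10.959   9.634 -11.849  1.00  0.00              
ATOM     45  N   ALA A  12      11.028   8.711  -9.811  1.00  0.00              
ATOM     46  CA  ALA A  12      12.464   8.914  -9.659  1.00  0.00              
ATOM     47  C   ALA A  12      12.832  10.386  -9.813  1.00  0.00              
ATOM     48  O   ALA A  12      13.773  10.729 -10.528  1.00  0.00              
END   
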