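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
ATOM     23  C   ALA A   6      15.625  10.294  -2.274  1.00  0.00              
ATOM     24  O   ALA A   6      16.038   9.948  -3.381  1.00  0.00              
ATOM     25  N   ALA A   7      16.452  10.645  -1.294  1.00  0.00              
ATOM     26  CA  ALA A   7      17.899  10.640  -1.474  1.00  0.00              
ATOM     27  C   ALA A   7      18.483  12.035  -1.278  1.00  0.00              
ATOM     28  O   ALA A   7      18.475  12.596  -0.182  1.00  0.00              
ATOM     29  N   ALA A   8      19.002  12.611  -2.358  1.00  0.00              
ATOM     30  CA  ALA A   8      19.593  13.943  -2.307  1.00  0.00              
ATOM     31  C   ALA A   8      21.067  13.908  -2.695  1.00  0.00              
ATOM     32  O   ALA A   8      21.432  13.631  -3.838  1.00  0.00              
ATOM     33  N   ALA A   9      21.935  14.194  -1.730  1.00  0.00              
ATOM     34  CA  ALA A   9      23.373  14.195  -1.970  1.00  0.00              
ATOM     35  C   ALA A   9      23.974  15.573  -1.711  1.00  0.00              
ATOM     36  O   ALA A   9      24.013  16.064  -0.583  1.00  0.00              
ATOM     37  N   ALA A  10      24.452  16.214  -2.773  1.00  0.00              
ATOM     38  CA  ALA A  10      25.052  17.538  -2.663  1.00  0.00              
ATOM     39  C   ALA A  10      26.509  17.522  -3.113  1.00  0.00              
ATOM     40  O   ALA A  10      26.803  17.313  -4.290  1.00  0.00              
END   
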