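ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       1.270   2.406   0.000  1.00  0.00              
ATOM      5  N   ALA A   2       3.333   1.538  -0.000  1.00  0.00              
ATOM      6  CA  ALA A   2       3.989   2.840  -0.000  1.00  0.00              
ATOM      7  C   ALA A   2       5.507   2.694  -0.000  1.00  0.00              
ATOM      8  O   ALA A   2       6.054   1.591  -0.000  1.00  0.00              
ATOM      9  N   ALA A   3       6.205   3.825  -0.000  1.00  0.00              
ATOM     10  CA  ALA A   3       7.663   3.825  -0.000  1.00  0.00              
ATOM     11  C   ALA A   3       8.214   5.247  -0.000  1.00  0.00              
ATOM     12  O   ALA A   3       7.475   6.231   0.000  1.00  0.00              
ATOM     13  N   ALA A   4       9.538   5.362  -0.000  1.00  0.00              
ATOM     14  CA  ALA A   4      10.193   6.665   0.000  1.00  0.00              
ATOM     15  C   ALA A   4      11.711   6.519  -0.000  1.00  0.00              
ATOM     16  O   ALA A   4      12.259   5.416  -0.000  1.00  0.00              
ATOM     17  N   ALA A   5      12.410   7.649  -0.000  1.00  0.00              
ATOM     18  CA  ALA A   5      13.868   7.649  -0.000  1.00  0.00              
ATOM     19  C   ALA A   5      14.419   9.071  -0.000  1.00  0.00              
ATOM     20  O   ALA A   5      13.680  10.056   0.000  1.00  0.00              
ATOM     21  N   ALA A   6      15.743   9.187  -0.000  1.00  0.00              
ATOM     22  CA  ALA A   6      16.398  10.490   0.000  1.00  0.00              
ATOM     23  C   ALA A   6      17.916  10.343  -0.000  1.00  0.00              
ATOM     24  O   ALA A   6      18.464   9.241  -0.000  1.00  0.00              
ATOM     25  N   ALA A   7      18.615  11.474  -0.000  1.00  0.00              
ATOM     26  CA  ALA A   7      20.073  11.474  -0.000  1.00  0.00              
ATOM     27  C   ALA A   7      20.624  12.896  -0.000  1.00  0.00              
ATOM     28  O   ALA A   7      19.885  13.880   0.000  1.00  0.00              
ATOM     29  N   ALA A   8      21.948  13.012  -0.000  1.00  0.00              
ATOM     30  CA  ALA A   8      22.603  14.314   0.000  1.00  0.00              
ATOM     31  C   ALA A   8      24.121  14.168  -0.000  1.00  0.00              
ATOM     32  O   ALA A   8      24.668  13.066  -0.000  1.00  0.00              
ATOM     33  N   ALA A   9      24.819  15.299  -0.000  1.00  0.00              
ATOM     34  CA  ALA A   9      26.277  15.299  -0.000  1.00  0.00              
ATOM     35  C   ALA A   9      26.829  16.721  -0.000  1.00  0.00              
ATOM     36  O   ALA A   9      26.090  17.705   0.000  1.00  0.00              
ATOM     37  N   ALA A  10      28.153  16.837  -0.000  1.00  0.00              
ATOM     38  CA  ALA A  10      28.808  18.139   0.000  1.00  0.00              
ATOM     39  C   ALA A  10      30.326  17.993  -0.000  1.00  0.00              
ATOM     40  O   ALA A  10      30.852  16.880  -0.000  1.00  0.00              
END   
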