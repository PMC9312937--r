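ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       1.481   2.325   0.649  1.00  0.00              
ATOM      5  N   ALA A   2       3.093   1.631  -0.740  1.00  0.00              
ATOM      6  CA  ALA A   2       3.720   2.944  -0.827  1.00  0.00              
ATOM      7  C   ALA A   2       4.722   3.153   0.304  1.00  0.00              
ATOM      8  O   ALA A   2       5.774   2.517   0.366  1.00  0.00              
ATOM      9  N   ALA A   3       4.394   4.060   1.218  1.00  0.00              
ATOM     10  CA  ALA A   3       5.264   4.356   2.350  1.00  0.00              
ATOM     11  C   ALA A   3       6.216   5.503   2.029  1.00  0.00              
ATOM     12  O   ALA A   3       7.078   5.875   2.826  1.00  0.00              
ATOM     13  N   ALA A   4       6.062   6.079   0.841  1.00  0.00              
ATOM     14  CA  ALA A   4       6.908   7.186   0.411  1.00  0.00              
ATOM     15  C   ALA A   4       8.332   6.717   0.132  1.00  0.00              
ATOM     16  O   ALA A   4       8.585   5.551  -0.171  1.00  0.00              
ATOM     17  N   ALA A   5       9.284   7.638   0.234  1.00  0.00              
ATOM     18  CA  ALA A   5      10.686   7.321  -0.008  1.00  0.00              
ATOM     19  C   ALA A   5      10.969   7.173  -1.499  1.00  0.00              
ATOM     20  O   ALA A   5      10.256   7.701  -2.352  1.00  0.00              
ATOM     21  N   ALA A   6      12.030   6.441  -1.825  1.00  0.00              
ATOM     22  CA  ALA A   6      12.411   6.221  -3.215  1.00  0.00              
ATOM     23  C   ALA A   6      13.017   7.480  -3.826  1.00  0.00              
ATOM     24  O   ALA A   6      14.148   7.867  -3.532  1.00  0.00              
ATOM     25  N   ALA A   7      12.254   8.136  -4.695  1.00  0.00              
ATOM     26  CA  ALA A   7      12.714   9.353  -5.352  1.00  0.00              
ATOM     27  C   ALA A   7      12.144   9.469  -6.761  1.00  0.00              
ATOM     28  O   ALA A   7      11.061   8.971  -7.068  1.00  0.00              
ATOM     29  N   ALA A   8      12.884  10.138  -7.640  1.00  0.00              
ATOM     30  CA  ALA A   8      12.454  10.322  -9.021  1.00  0.00              
ATOM     31  C   ALA A   8      11.511  11.513  -9.152  1.00  0.00              
ATOM     32  O   ALA A   8      11.951  12.646  -9.347  1.00  0.00              
END   
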