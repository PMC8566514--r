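# haloscreen embedded isotope constants, v1 (NIST/CODATA atomic masses and
# representative isotopic abundances; electron mass 0.000548579909 Da)
element,isotope,mass_da,abundance,nominal
H,1H,1.00782503207,0.999885,1
H,2H,2.01410177785,0.000115,2
C,12C,12.0000000000,0.9893,12
C,13C,13.00335483507,0.0107,13
N,14N,14.00307400443,0.99636,14
N,15N,15.00010889888,0.00364,15
O,16O,15.99491461957,0.99757,16
O,17O,16.99913175650,0.00038,17
O,18O,17.99915961286,0.00205,18
S,32S,31.97207117440,0.9499,32
S,33S,32.97145890980,0.0075,33
S,34S,33.96786700400,0.0425,34
S,36S,35.96708071000,0.0001,36
Cl,35Cl,34.96885268200,0.7576,35
Cl,37Cl,36.96590260200,0.2424,37
Br,79Br,78.91833710000,0.5069,79
Br,81Br,80.91628970000,0.4931,81
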