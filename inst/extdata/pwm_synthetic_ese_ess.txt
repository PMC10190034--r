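# Synthetic ESE/ESS position weight matrices (log-odds convention).
#
# These are consensus-derived stand-in matrices for the five SR-protein
# exonic splicing enhancer motifs and the hnRNP A1 exonic splicing
# silencer, NOT the experimentally derived ESEFinder SELEX / iCLIP
# matrices. They reproduce the degenerate consensus patterns and widths of
# the real motifs so the scoring machinery is exercised realistically;
# replace this file with the published matrices for production use (same
# format). Score thresholds are the published ESEFinder defaults where
# they exist.
#
# Format: header "NAME WIDTH ROLE THRESHOLD", then WIDTH rows of four
# whitespace-separated weights in A C G T order.

SRSF1_syn 7 enhancer 1.956
-1.10 1.20 0.80 -1.30
1.10 -1.00 0.70 -1.40
-1.20 1.10 0.90 -1.10
1.40 -0.90 -0.60 -1.20
-1.00 0.90 1.20 -1.30
-1.10 -1.20 1.50 -1.40
1.30 -0.80 -0.50 -1.10

SRSF1_igM_BRCA2_syn 7 enhancer 1.867
-0.90 1.10 0.90 -1.20
1.00 -0.90 0.80 -1.30
-1.10 1.30 0.70 -1.00
1.30 -0.80 -0.70 -1.10
-0.90 1.10 1.00 -1.20
-1.00 -1.10 1.40 -1.30
1.20 -0.70 -0.60 -1.00

SRSF2_syn 8 enhancer 2.383
-0.80 -0.90 1.30 -1.10
0.90 -1.00 0.80 -1.20
-1.00 1.10 -0.90 0.90
-1.10 1.00 -0.80 0.80
-0.90 1.40 -1.00 -0.70
-1.00 0.80 1.10 -1.20
-0.90 1.00 -1.10 0.90
0.80 -0.90 0.70 -1.00
SRSF5_syn 7 enhancer 2.67
-1.00 0.90 -0.80 1.10
1.20 -0.90 -0.70 -1.10
-0.90 1.30 0.60 -1.20
1.10 -0.80 0.90 -1.00
-1.10 1.00 0.80 -0.90
-0.80 -1.00 1.30 -1.10
-0.90 1.10 0.70 -1.00
SRSF6_syn 6 enhancer 2.676
-1.00 -0.90 0.80 1.20
-0.90 0.70 1.30 -1.10
-0.80 1.10 -0.90 0.90
-1.00 -0.80 1.40 -1.20
-0.90 0.90 0.80 1.00
-0.70 1.20 -1.00 0.80

hnRNPA1_syn 6 silencer 1.500
-1.20 -1.00 -0.90 1.40
1.50 -1.10 -1.00 -1.30
-1.30 -1.20 1.60 -1.10
-1.20 -1.10 1.50 -1.00
-1.10 -1.00 1.40 -0.90
0.90 -0.80 -0.70 0.80
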