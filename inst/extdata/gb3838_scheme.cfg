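# Surface-water class limits, GB 3838-2002 (units mg/L unless noted).
# Format: indicator: direction b1 b2 b3 b4 b5
#   higher_is_worse  boundaries are upper limits of classes I..V
#   lower_is_worse   boundaries are lower limits of classes I..V
#   range            two-sided acceptable interval (in range -> I)
#   none             no class limits; skipped by grading
# TP uses the river limits. BOD5 classes I and II share one limit in the
# standard. WT and turbidity carry no class limits.
COD_Mn: higher_is_worse 2 4 6 10 15
BOD5: higher_is_worse 3 3 4 6 10
NH4: higher_is_worse 0.15 0.5 1.0 1.5 2.0
TP: higher_is_worse 0.02 0.1 0.2 0.3 0.4
TN: higher_is_worse 0.2 0.5 1.0 1.5 2.0
DO: lower_is_worse 7.5 6 5 3 2
PH: range 6 9
WT: none
Tub: none
CHL: none
CA: none
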