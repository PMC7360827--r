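# Synthetic gene-pool archetypes for simulated common-bean collections.
#
# These are invented simulation defaults, informed by published group
# profiles of the two domesticated gene pools (Andean: large speckled
# seeds, erect/determinate habit, pale flowers, short maturity;
# Mesoamerican: small speckle-free seeds, prostrate/indeterminate habit,
# plain dark or pale coats, taller later plants). They are NOT estimates
# from any real accession panel.
#
# quantitative: per trait {mean, sd} in catalog units. LWS is derived as
#   SL/SW after sampling and is deliberately absent here.
# qualitative: per trait a probability vector over the catalog's declared
#   levels, in catalog order.
andean:
  name: Andean
  quantitative:
    DF:  {mean: 45.0, sd: 5.0}
    DM:  {mean: 71.0, sd: 4.0}
    PH:  {mean: 55.0, sd: 10.0}
    NS:  {mean: 8.0,  sd: 1.5}
    NB:  {mean: 5.0,  sd: 1.0}
    NP:  {mean: 7.3,  sd: 1.5}
    PL:  {mean: 12.0, sd: 1.5}
    PW:  {mean: 1.2,  sd: 0.15}
    NSP: {mean: 5.0,  sd: 1.0}
    SL:  {mean: 1.6,  sd: 0.15}
    SW:  {mean: 0.9,  sd: 0.08}
    HSW: {mean: 42.0, sd: 5.0}
  qualitative:
    HP:   [0.75, 0.25]
    GH:   [0.85, 0.15]
    PHA:  [0.80, 0.20]
    ST:   [0.90, 0.10]
    LS:   [0.85, 0.15]
    CS:   [0.45, 0.30, 0.15, 0.02, 0.08]
    CW:   [0.50, 0.25, 0.15, 0.02, 0.08]
    PC:   [0.10, 0.55, 0.20, 0.15]
    SP:   [0.05, 0.55, 0.15, 0.05, 0.05, 0.05, 0.05, 0.05]
    SPA:  [0.80, 0.20]
    PS:   [0.60, 0.25, 0.15]
    SS:   [0.35, 0.30, 0.05, 0.02, 0.03, 0.15, 0.05, 0.05]
    SCC:  [0.40, 0.05, 0.05, 0.02, 0.10, 0.05, 0.15, 0.03, 0.05, 0.10]
    SSC:  [0.05, 0.50, 0.30, 0.15]
    CSSC: [0.05, 0.20, 0.35, 0.10, 0.10, 0.20]
    HC:   [0.40, 0.30, 0.30]
mesoamerican:
  name: Mesoamerican
  quantitative:
    DF:  {mean: 40.0,  sd: 5.0}
    DM:  {mean: 79.0,  sd: 4.0}
    PH:  {mean: 170.0, sd: 35.0}
    NS:  {mean: 14.0,  sd: 3.0}
    NB:  {mean: 4.0,   sd: 1.0}
    NP:  {mean: 10.3,  sd: 2.0}
    PL:  {mean: 10.0,  sd: 1.5}
    PW:  {mean: 0.9,   sd: 0.12}
    NSP: {mean: 6.0,   sd: 1.0}
    SL:  {mean: 1.0,   sd: 0.12}
    SW:  {mean: 0.6,   sd: 0.06}
    HSW: {mean: 22.0,  sd: 4.0}
  qualitative:
    HP:   [0.45, 0.55]
    GH:   [0.05, 0.95]
    PHA:  [0.10, 0.90]
    ST:   [0.55, 0.45]
    LS:   [0.60, 0.40]
    CS:   [0.10, 0.08, 0.07, 0.40, 0.35]
    CW:   [0.10, 0.08, 0.07, 0.40, 0.35]
    PC:   [0.25, 0.30, 0.25, 0.20]
    SP:   [0.05, 0.10, 0.10, 0.50, 0.10, 0.05, 0.05, 0.05]
    SPA:  [0.90, 0.10]
    PS:   [0.70, 0.20, 0.10]
    SS:   [0.05, 0.10, 0.05, 0.02, 0.03, 0.10, 0.55, 0.10]
    SCC:  [0.02, 0.20, 0.30, 0.30, 0.03, 0.05, 0.01, 0.05, 0.03, 0.01]
    SSC:  [0.92, 0.04, 0.02, 0.02]
    CSSC: [0.92, 0.02, 0.01, 0.02, 0.02, 0.01]
    HC:   [0.45, 0.40, 0.15]
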