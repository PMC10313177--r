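# Synthetic stand-in for deconvolution-derived relative immune-cell
# abundance of metastases versus matched primary tumours.
# ratio = cell fraction in metastasis / cell fraction in matched primary.
# Qualitative directions: lymphocyte fractions reduced in metastases,
# myeloid fractions near or above parity. MDSC rows are monocyte-proxied.
# Wide tolerances; replace with your own estimates for real calibrations.
cell_type,site,estimator,ratio,tolerance
tcyt,lung,synthetic,0.55,0.30
th,lung,synthetic,0.60,0.30
treg,lung,synthetic,0.70,0.35
m1,lung,synthetic,0.90,0.40
m2,lung,synthetic,1.15,0.45
mdsc,lung,synthetic,1.10,0.45
apc,lung,synthetic,0.80,0.40
tcyt,other,synthetic,0.45,0.30
th,other,synthetic,0.50,0.30
treg,other,synthetic,0.65,0.35
m1,other,synthetic,0.80,0.40
m2,other,synthetic,1.20,0.45
mdsc,other,synthetic,1.15,0.45
apc,other,synthetic,0.70,0.40
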